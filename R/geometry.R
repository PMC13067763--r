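#' Read a structure model into an atom tibble
#'
#' Thin wrapper over `bio3d::read.pdb()`: keeps the first model, prefers
#' altloc `A` (or blank), and returns a plain atom table usable by the
#' distance functions.
#'
#' @param path Path to a PDB file.
#' @return A tibble of class `structure_model`: `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z` (ångström).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  if ("alt" %in% names(at)) {
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  }
  structure_model(tibble(
    chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, x = at$x, y = at$y, z = at$z))
}

#' Construct / validate a structure model
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @return The validated tibble with class `structure_model`.
#' @export
structure_model <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(sprintf("atoms need columns %s.", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom coordinates must be finite.")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) abort("(chain, resno, elety) must be unique.")
  structure(atoms, class = c("structure_model", class(atoms)))
}

# side-chain reference atom per residue type: the charged/functional tip for
# Lys and Tyr, CB otherwise (CA for Gly, which has no CB)
sidechain_atom <- function(resid) {
  switch(toupper(resid), LYS = "NZ", TYR = "OH", GLY = "CA", "CB")
}

residue_xyz <- function(model, resno, atom_rule, chain = NULL) {
  at <- model[model$resno == resno, , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) abort(sprintf("residue %s not found in model.", resno))
  resid <- at$resid[1]
  want <- if (atom_rule == "ca") "CA" else sidechain_atom(resid)
  hit <- at[at$elety == want, , drop = FALSE]
  if (nrow(hit) == 0L) {
    abort(sprintf("atom %s missing for residue %s%s.", want, resid, resno))
  }
  c(hit$x[1], hit$y[1], hit$z[1])
}

#' Distance between two residues
#'
#' Euclidean distance between rule-selected atoms of two residues. The
#' default `"sidechain"` rule uses the side-chain reference atom (NZ for
#' lysine, OH for tyrosine, CB otherwise, CA for glycine); `"ca"` uses
#' alpha carbons.
#'
#' @param model A [structure_model()].
#' @param resA,resB Residue numbers.
#' @param atom_rule `"sidechain"` (default) or `"ca"`.
#' @param chain Optional chain filter.
#' @return Distance in ångström.
#' @export
residue_distance <- function(model, resA, resB,
                             atom_rule = c("sidechain", "ca"),
                             chain = NULL) {
  atom_rule <- match.arg(atom_rule)
  a <- residue_xyz(model, resA, atom_rule, chain)
  b <- residue_xyz(model, resB, atom_rule, chain)
  sqrt(sum((a - b)^2))
}

#' Pairwise distance panel over pocket-entrance residues
#'
#' All pairwise distances among a set of gatekeeper residues (default the
#' pocket-entrance cluster 31, 76, 84, 106), with the atom-selection rule
#' recorded.
#'
#' @inheritParams residue_distance
#' @param gatekeepers Residue numbers (at least two; default
#'   `c(31, 76, 84, 106)`).
#' @return Tibble of class `distance_panel`: `resA`, `resB`, `distance`;
#'   attribute `atom_rule`.
#' @export
entrance_panel <- function(model, gatekeepers = c(31L, 76L, 84L, 106L),
                           atom_rule = c("sidechain", "ca"), chain = NULL) {
  atom_rule <- match.arg(atom_rule)
  if (length(gatekeepers) < 2L) abort("need at least two residues.")
  pairs <- utils::combn(sort(gatekeepers), 2)
  out <- map(seq_len(ncol(pairs)), function(i) {
    tibble(resA = pairs[1, i], resB = pairs[2, i],
           distance = residue_distance(model, pairs[1, i], pairs[2, i],
                                       atom_rule, chain))
  }) %>% bind_rows()
  structure(out, class = c("distance_panel", class(out)),
            atom_rule = atom_rule)
}

#' Aggregate replicate pocket areas for an alanine scan
#'
#' For each scanned position, averages the pocket surface areas obtained
#' from independently predicted structures (five per position in the
#' reference protocol) and ranks positions by mean area, largest first.
#' Ties go to the lower residue number. The rank-1 position is the key
#' site candidate.
#'
#' @param areas Tibble with columns `position` and `area` (one row per
#'   replicate; a `replicate` column is allowed and ignored).
#' @return Tibble of class `pocket_scan`: `position`, `n_replicates`,
#'   `mean_area`, `rank`, sorted by rank; attribute `key_site`.
#' @export
aggregate_alanine_scan <- function(areas) {
  areas <- as_tibble(areas)
  if (!all(c("position", "area") %in% names(areas)) || nrow(areas) == 0L) {
    abort("`areas` needs at least one row with columns position, area.")
  }
  out <- areas %>%
    group_by(.data$position) %>%
    summarise(n_replicates = dplyr::n(),
              mean_area = mean(.data$area), .groups = "drop") %>%
    arrange(desc(.data$mean_area), .data$position) %>%
    mutate(rank = dplyr::row_number())
  structure(out, class = c("pocket_scan", class(out)),
            key_site = out$position[1])
}

#' @export
print.pocket_scan <- function(x, ...) {
  cat("<pocket_scan> ", nrow(x), " positions; key site = ",
      attr(x, "key_site"), " (mean area ",
      sprintf("%.1f", x$mean_area[1]), " Å²)\n", sep = "")
  NextMethod()
}

#' Trilaterate a point from three anchor distances
#'
#' Finds the points of 3-space at given distances from three non-collinear
#' anchors (the intersection of three spheres): two mirror solutions in the
#' generic case, one when the point lies in the anchor plane, none when the
#' distances are inconsistent. Solutions are accepted when each sphere
#' equation is met within `tol` (ångström).
#'
#' @param anchors 3x3 numeric matrix, one anchor per row.
#' @param distances Positive distances to the three anchors.
#' @param tol Residual tolerance in ångström (default 1e-6).
#' @return Matrix with 0, 1 or 2 rows (candidate points); attribute
#'   `residuals` reports the best per-sphere residuals when empty.
#' @examples
#' trilaterate(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'             c(1, sqrt(2), sqrt(2)))
#' @export
trilaterate <- function(anchors, distances, tol = 1e-6) {
  anchors <- as.matrix(anchors)
  if (!all(dim(anchors) == c(3L, 3L)) || any(!is.finite(anchors))) {
    abort("`anchors` must be a finite 3x3 matrix (one point per row).")
  }
  if (length(distances) != 3L || any(!is.finite(distances)) ||
      any(distances <= 0)) {
    abort("`distances` must be three positive finite numbers.")
  }
  p1 <- anchors[1, ]; p2 <- anchors[2, ]; p3 <- anchors[3, ]
  ex_raw <- p2 - p1
  d <- sqrt(sum(ex_raw^2))
  cr <- c(ex_raw[2] * (p3 - p1)[3] - ex_raw[3] * (p3 - p1)[2],
          ex_raw[3] * (p3 - p1)[1] - ex_raw[1] * (p3 - p1)[3],
          ex_raw[1] * (p3 - p1)[2] - ex_raw[2] * (p3 - p1)[1])
  if (d < 1e-9 || sqrt(sum(cr^2)) / max(d, 1) < 1e-9) {
    abort("anchors are collinear (or coincident); trilateration is degenerate.")
  }
  ex <- ex_raw / d
  i <- sum(ex * (p3 - p1))
  ey_raw <- (p3 - p1) - i * ex
  ey <- ey_raw / sqrt(sum(ey_raw^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  j <- sum(ey * (p3 - p1))
  r1 <- distances[1]; r2 <- distances[2]; r3 <- distances[3]
  x <- (r1^2 - r2^2 + d^2) / (2 * d)
  y <- (r1^2 - r3^2 + i^2 + j^2 - 2 * i * x) / (2 * j)
  z2 <- r1^2 - x^2 - y^2
  cands <- if (z2 > 0) {
    z <- sqrt(z2)
    rbind(p1 + x * ex + y * ey + z * ez,
          p1 + x * ex + y * ey - z * ez)
  } else {
    rbind(p1 + x * ex + y * ey)
  }
  resid <- apply(cands, 1, function(pt) {
    max(abs(sqrt(colSums((t(anchors) - pt)^2)) - distances))
  })
  ok <- resid <= tol
  out <- cands[ok, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  if (nrow(out) == 2L && sqrt(sum((out[1, ] - out[2, ])^2)) <= tol) {
    out <- out[1, , drop = FALSE]
  }
  attr(out, "residuals") <- resid
  out
}
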