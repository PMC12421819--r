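# Natural-abundance correction for TBDMS-derivatized amino-acid fragments.
#
# The correction covers derivatization atoms and non-backbone carbons only;
# natural 13C of the tracer (backbone) carbons is excluded by convention,
# so corrected MIDs are directly comparable with simulated tracer MIDs.

#' Natural isotope abundances
#'
#' Mass-shift probability vectors per element (shift 0, +1, +2 relative to
#' the lightest isotope), IUPAC representative values.
#'
#' @return named list of numeric vectors.
#' @export
natural_abundance <- function() {
  list(C = c(0.9893, 0.0107),
       H = c(0.999885, 0.000115),
       N = c(0.99636, 0.00364),
       O = c(0.99757, 0.00038, 0.00205),
       Si = c(0.92223, 0.04685, 0.03092),
       S = c(0.9499, 0.0075, 0.0425))
}

#' Fragment specification for a derivatized amino acid
#'
#' @param amino_acid amino-acid name.
#' @param nominal_mass integer fragment m/z.
#' @param backbone_carbons carbons of the amino-acid backbone contained in
#'   the fragment (the packaged fragments contain the complete backbone).
#' @param elemental_formula named integer vector, element -> atom count of
#'   the whole derivatized fragment (including backbone carbons).
#' @return a `c1_fragment`.
#' @export
fragment_spec <- function(amino_acid, nominal_mass, backbone_carbons,
                          elemental_formula) {
  stopifnot(nominal_mass > 0, backbone_carbons >= 1)
  if (!"C" %in% names(elemental_formula) ||
      elemental_formula[["C"]] < backbone_carbons) {
    stop("elemental formula must contain at least the backbone carbons")
  }
  structure(list(amino_acid = amino_acid,
                 nominal_mass = as.integer(nominal_mass),
                 backbone_carbons = as.integer(backbone_carbons),
                 elemental_formula = elemental_formula),
            class = "c1_fragment")
}

#' Default TBDMS fragment library
#'
#' The [M-57]+ fragments of TBDMS-derivatized alanine (m/z 260), glycine
#' (246), serine (390), aspartate (418) and glutamate (432), all containing
#' the complete amino-acid carbon backbone. The elemental formulas are
#' editable defaults for the standard TBDMS chemistry (2 TBDMS groups for
#' Ala/Gly, 3 for Ser/Asp/Glu), not values reported by any single study.
#'
#' @return named list of `c1_fragment`s.
#' @export
default_fragments <- function() {
  list(
    Ala = fragment_spec("Ala", 260, 3, c(C = 11, H = 26, N = 1, O = 2, Si = 2)),
    Gly = fragment_spec("Gly", 246, 2, c(C = 10, H = 24, N = 1, O = 2, Si = 2)),
    Ser = fragment_spec("Ser", 390, 3, c(C = 17, H = 40, N = 1, O = 3, Si = 3)),
    Asp = fragment_spec("Asp", 418, 4, c(C = 18, H = 40, N = 1, O = 4, Si = 3)),
    Glu = fragment_spec("Glu", 432, 5, c(C = 19, H = 42, N = 1, O = 4, Si = 3))
  )
}

convolve_dists <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

self_convolve <- function(p, n) {
  out <- 1
  for (i in seq_len(n)) out <- convolve_dists(out, p)
  out
}

#' Build a natural-abundance correction matrix
#'
#' Column j (zero-based mass shift j of the tracer labels) holds the
#' probability that a molecule with j tracer 13C atoms is observed at mass
#' shift i, obtained by convolving the isotope distributions of all
#' non-tracer atoms: the derivatization/side atoms (H, N, O, Si, ...) and
#' the non-backbone carbons. Backbone (tracer) carbons are excluded.
#'
#' @param spec a `c1_fragment`.
#' @param abundance_table element -> isotope probability vector; defaults
#'   to [natural_abundance()].
#' @return an `(n+1) x (n+1)` matrix, n = backbone carbons, class
#'   `c1_correction`.
#' @export
build_correction_matrix <- function(spec, abundance_table = natural_abundance()) {
  formula <- spec$elemental_formula
  nb <- spec$backbone_carbons
  nat <- 1
  for (el in names(formula)) {
    cnt <- formula[[el]]
    if (el == "C") cnt <- cnt - nb  # tracer carbons excluded
    if (cnt == 0) next
    if (!el %in% names(abundance_table)) {
      stop("element missing from abundance table: ", el)
    }
    p <- abundance_table[[el]]
    if (abs(sum(p) - 1) > 1e-6) stop("abundances for ", el, " do not sum to 1")
    nat <- convolve_dists(nat, self_convolve(p, cnt))
  }
  # pad the mass window beyond the tracer shifts until the natural
  # envelope of the heaviest column is >= 99.9% captured
  pad <- 0L
  while (sum(nat[seq_len(min(pad + 1L, length(nat)))]) < 0.999 &&
         pad + 1L < length(nat)) {
    pad <- pad + 1L
  }
  nrows <- nb + 1L + pad
  ncols <- nb + 1L
  C <- matrix(0, nrows, ncols)
  for (j in seq_len(ncols)) {
    take <- seq_len(min(length(nat), nrows - j + 1L))
    C[(j - 1L) + take, j] <- nat[take]
  }
  rownames(C) <- paste0("M", 0:(nrows - 1L))
  colnames(C) <- paste0("M", 0:nb)
  structure(C, class = c("c1_correction", "matrix", "array"),
            fragment = spec$amino_acid)
}

#' Convolve a tracer MID with natural abundance
#' @param x tracer MID (length n+1).
#' @param C a correction matrix from [build_correction_matrix()].
#' @return raw (observed-scale) MID, renormalised over the retained mass
#'   window.
#' @export
convolve_mid <- function(x, C) {
  y <- as.numeric(unclass(C) %*% x)
  y / sum(y)
}

#' Correct a raw MID for natural abundance
#'
#' Solves `C x ~ raw` by non-negative least squares (via quadprog) and
#' renormalises; NNLS is robust to the truncation of the mass window that
#' makes `C` slightly column-deficient.
#'
#' @param raw measured MID, normalised to sum 1.
#' @param C correction matrix.
#' @return corrected MID with attributes `residual` (||Cx - raw||) and
#'   `raw_fit`.
#' @export
correct_mid <- function(raw, C) {
  C <- unclass(C)
  if (length(raw) != nrow(C)) stop("MID length does not match matrix")
  if (sum(raw) <= 0) stop("all-zero raw MID")
  raw <- raw / sum(raw)
  D <- crossprod(C) + diag(1e-12, ncol(C))
  d <- crossprod(C, raw)
  sol <- quadprog::solve.QP(D, d, diag(ncol(C)), rep(0, ncol(C)))
  x <- pmax(sol$solution, 0)
  fit <- as.numeric(C %*% x)
  out <- x / sum(x)
  attr(out, "residual") <- sqrt(sum((fit - raw)^2))
  names(out) <- colnames(C)
  out
}

#' Read / write raw MID CSV (fragment, M0..Mn columns)
#' @param path CSV path.
#' @return named list of MID vectors.
#' @export
read_mid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  mcols <- grep("^M\\d+$", names(df), value = TRUE)
  for (i in seq_len(nrow(df))) {
    v <- as.numeric(df[i, mcols])
    out[[df$fragment[i]]] <- v[!is.na(v)]
  }
  out
}

#' @rdname read_mid_csv
#' @param mids named list of MID vectors.
#' @export
write_mid_csv <- function(mids, path) {
  nmax <- max(vapply(mids, length, 0L)) - 1L
  df <- do.call(rbind, lapply(names(mids), function(f) {
    v <- mids[[f]]
    as.data.frame(c(list(fragment = f),
                    as.list(stats::setNames(c(v, rep(NA, nmax + 1L - length(v))),
                                            paste0("M", 0:nmax)))),
                  stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
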