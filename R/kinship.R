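#' VanRaden genomic relationship matrix
#'
#' Method-1 VanRaden GRM: with dosage matrix M (0/1/2) and base allele
#' frequencies p, Z = M - 2p (column-centered) and
#' G = Z Z' / (2 sum p (1 - p)). Markers monomorphic under the base
#' frequencies (p = 0 or 1) are excluded from both numerator and
#' denominator.
#'
#' Base frequencies may be supplied (e.g. fixed founder-panel frequencies,
#' so inbreeding is tracked relative to the initial diversity) or estimated
#' from the data (`"from-data"`).
#'
#' @param dos integer dosage matrix (individuals x markers) with values in
#'   0/1/2; row names are used as individual ids.
#' @param base_freqs per-marker allele frequency of the counted allele, or
#'   `"from-data"` to use column means / 2.
#' @return an object of class `saf_grm`: list with `values` (symmetric
#'   n x n), `base_freqs`, and `ids`.
#' @export
compute_grm <- function(dos, base_freqs = "from-data") {
  stopifnot(is.matrix(dos))
  if (!all(dos %in% c(0L, 1L, 2L))) stop("dosages must be coded 0/1/2")
  if (identical(base_freqs, "from-data")) {
    base_freqs <- colMeans(dos) / 2
  }
  stopifnot(length(base_freqs) == ncol(dos))
  use <- base_freqs > 0 & base_freqs < 1
  if (!any(use)) stop("all markers are monomorphic under the base frequencies")
  p <- base_freqs[use]
  Z <- sweep(dos[, use, drop = FALSE], 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  ids <- rownames(dos)
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(dos)))
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, base_freqs = base_freqs, ids = ids),
            class = "saf_grm")
}

#' @export
print.saf_grm <- function(x, ...) {
  cat("VanRaden GRM over", length(x$ids), "individuals; mean diagonal",
      round(mean(diag(x$values)), 3), "\n")
  invisible(x)
}

#' Inbreeding coefficient from a GRM
#'
#' F is the mean of the GRM diagonal minus 1: 0 for a non-inbred population
#' in Hardy-Weinberg proportions at the base frequencies, rising toward 1 as
#' homozygosity (relative to the base) accumulates.
#'
#' @param grm a `saf_grm` or a square numeric matrix.
#' @return scalar F.
#' @export
inbreeding_coefficient <- function(grm) {
  v <- if (inherits(grm, "saf_grm")) grm$values else grm
  stopifnot(is.matrix(v), nrow(v) == ncol(v), nrow(v) > 0)
  mean(diag(v)) - 1
}

#' Rate of inbreeding between consecutive cycles
#'
#' @param F_i inbreeding coefficient at cycle i.
#' @param F_j inbreeding coefficient at cycle j = i + 1.
#' @return `F_j - F_i`.
#' @export
delta_F <- function(F_i, F_j) F_j - F_i

#' Write / read a GRM as square CSV (lossless round trip)
#' @param grm a `saf_grm`.
#' @param path file path.
#' @export
write_grm_csv <- function(grm, path) {
  df <- data.frame(id = grm$ids, grm$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  bf <- file.path(dirname(path),
                  sub("(\\.csv)?$", "_base_freqs.csv", basename(path)))
  mk <- names(grm$base_freqs)
  if (is.null(mk)) mk <- NA_character_
  write.csv(data.frame(marker = mk, freq = grm$base_freqs), bf,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_csv
#' @export
read_grm_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ids <- df$id
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(ids, ids)
  bf <- file.path(dirname(path),
                  sub("(\\.csv)?$", "_base_freqs.csv", basename(path)))
  freqs <- if (file.exists(bf)) {
    fdf <- read.csv(bf)
    setNames(fdf$freq, if (all(is.na(fdf$marker))) NULL else fdf$marker)
  } else NULL
  structure(list(values = v, base_freqs = freqs, ids = ids),
            class = "saf_grm")
}
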