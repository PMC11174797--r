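#' Genetic map
#'
#' A marker map over a set of chromosomes with positions in Morgans. The
#' default layout mirrors safflower (n = 12 chromosomes), each 1 Morgan long
#' with markers evenly spaced; any per-chromosome lengths and explicit
#' positions are accepted.
#'
#' @param n_markers number of markers to place (ignored when `chr`/`pos` are
#'   given).
#' @param n_chromosomes number of chromosomes.
#' @param lengths per-chromosome length in Morgans (recycled if scalar).
#' @param chr,pos optional explicit assignment: integer chromosome index and
#'   position in Morgans per marker. Markers must be grouped by chromosome
#'   with non-decreasing positions.
#' @param marker_ids optional marker names.
#' @return an object of class `saf_map`.
#' @export
genetic_map <- function(n_markers = NULL, n_chromosomes = 12,
                        lengths = 1, chr = NULL, pos = NULL,
                        marker_ids = NULL) {
  if (is.null(chr)) {
    stopifnot(is.numeric(n_markers), n_markers >= 1)
    lengths <- rep_len(lengths, n_chromosomes)
    per <- diff(floor(seq(0, n_markers, length.out = n_chromosomes + 1)))
    chr <- rep.int(seq_len(n_chromosomes), per)
    pos <- unlist(lapply(seq_len(n_chromosomes), function(c) {
      k <- per[c]
      if (k == 0) return(numeric(0))
      lengths[c] * (seq_len(k) - 0.5) / k
    }), use.names = FALSE)
  } else {
    stopifnot(length(chr) == length(pos))
    n_chromosomes <- max(chr)
    lengths <- rep_len(lengths, n_chromosomes)
    n_markers <- length(chr)
  }
  if (is.unsorted(chr)) stop("markers must be grouped by chromosome, in order")
  for (c in unique(chr)) {
    p <- pos[chr == c]
    if (is.unsorted(p)) stop("positions must be non-decreasing within a chromosome")
    if (any(p < 0) || any(p > lengths[c]))
      stop("positions must lie within [0, chromosome length]")
  }
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(n_markers))
  stopifnot(length(marker_ids) == n_markers, !anyDuplicated(marker_ids))
  idx <- split(seq_len(n_markers), factor(chr, levels = seq_len(n_chromosomes)))
  structure(list(
    n_chromosomes = n_chromosomes,
    lengths = as.numeric(lengths),
    chr = as.integer(chr),
    pos = as.numeric(pos),
    marker_ids = marker_ids,
    chr_start = vapply(idx, function(i) if (length(i)) min(i) else 1L, 1L),
    chr_end = vapply(idx, function(i) if (length(i)) max(i) else 0L, 1L)
  ), class = "saf_map")
}

#' @export
print.saf_map <- function(x, ...) {
  cat("Genetic map:", length(x$pos), "markers on", x$n_chromosomes,
      "chromosomes,", sum(x$lengths), "Morgans total\n")
  invisible(x)
}

n_markers_map <- function(map) length(map$pos)

#' Population of phased diploid individuals
#'
#' Haplotypes are stored as a (2n x m) 0/1 integer matrix with rows 2i-1 and
#' 2i holding the two haplotypes of individual i; the dosage of individual i
#' is their sum (0/1/2). Pedigree links and a generation label are carried
#' along.
#'
#' @param haplo integer matrix of haplotypes, 2n rows by m markers.
#' @param map a [genetic_map()] over the same m markers.
#' @param id individual identifiers (unique); autogenerated if `NULL`.
#' @param parents n x 2 character matrix of parent ids (`NA` for founders).
#' @param generation generation label(s) (e.g. "founder", "F1", "F4").
#' @return an object of class `saf_pop`.
#' @export
new_population <- function(haplo, map, id = NULL, parents = NULL,
                           generation = "founder") {
  stopifnot(is.matrix(haplo), nrow(haplo) %% 2 == 0)
  if (ncol(haplo) != n_markers_map(map))
    stop("haplotype length does not match the map's marker count")
  if (!all(haplo %in% c(0L, 1L))) stop("haplotypes must be 0/1")
  n <- nrow(haplo) / 2L
  if (is.null(id)) id <- paste0("I", seq_len(n))
  if (anyDuplicated(id)) stop("individual ids must be unique")
  stopifnot(length(id) == n)
  if (is.null(parents)) parents <- matrix(NA_character_, n, 2)
  generation <- rep_len(generation, n)
  structure(list(haplo = haplo, map = map, id = as.character(id),
                 parents = parents, generation = generation),
            class = "saf_pop")
}

#' @export
print.saf_pop <- function(x, ...) {
  cat("Population:", n_ind(x), "individuals x", n_markers_map(x$map),
      "markers (", paste(unique(x$generation), collapse = "/"), ")\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `saf_pop`.
#' @export
n_ind <- function(pop) length(pop$id)

#' Genotype dosages of a population
#'
#' @param pop a `saf_pop`.
#' @return integer matrix (individuals x markers) of 0/1/2 allele dosages,
#'   with individual ids as row names and marker ids as column names.
#' @export
dosages <- function(pop) {
  h <- pop$haplo
  n <- nrow(h) / 2L
  d <- h[seq(1, 2 * n, by = 2), , drop = FALSE] +
    h[seq(2, 2 * n, by = 2), , drop = FALSE]
  dimnames(d) <- list(pop$id, pop$map$marker_ids)
  d
}

#' Subset a population by individual
#' @param x a `saf_pop`.
#' @param i integer indices, logical mask, or ids.
#' @param ... unused.
#' @export
`[.saf_pop` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  i <- seq_len(n_ind(x))[i]
  if (anyNA(i)) stop("unknown individual")
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  new_population(x$haplo[rows, , drop = FALSE], x$map, x$id[i],
                 x$parents[i, , drop = FALSE], x$generation[i])
}

#' Combine populations over the same map
#' @param ... `saf_pop` objects sharing one map.
#' @export
combine_pops <- function(...) {
  pops <- list(...)
  if (length(pops) == 1 && is.list(pops[[1]]) && !inherits(pops[[1]], "saf_pop"))
    pops <- pops[[1]]
  m0 <- pops[[1]]$map
  for (p in pops) {
    if (!identical(p$map$marker_ids, m0$marker_ids))
      stop("populations must share the same marker set and map")
  }
  new_population(do.call(rbind, lapply(pops, `[[`, "haplo")), m0,
                 unlist(lapply(pops, `[[`, "id")),
                 do.call(rbind, lapply(pops, `[[`, "parents")),
                 unlist(lapply(pops, `[[`, "generation")))
}

# low-level batch meiosis: one gamete per entry of parent_idx (1-based)
make_gametes <- function(pop, parent_idx) {
  map <- pop$map
  meiosis_batch_cpp(pop$haplo, as.integer(parent_idx) - 1L,
                    as.integer(map$chr_start) - 1L,
                    as.integer(map$chr_end) - 1L,
                    map$pos, map$lengths)
}

#' Simulate one gamete by meiosis
#'
#' Per chromosome the number of crossovers is Poisson with mean equal to the
#' chromosome length in Morgans, crossover positions are uniform along the
#' chromosome (no interference), and the starting haplotype is chosen by a
#' fair coin flip.
#'
#' @param pop a `saf_pop`.
#' @param parent individual index or id within `pop`.
#' @return integer 0/1 vector of length m (one haplotype).
#' @export
make_gamete <- function(pop, parent) {
  if (is.character(parent)) parent <- match(parent, pop$id)
  if (is.na(parent) || parent < 1 || parent > n_ind(pop))
    stop("unknown parent")
  drop(make_gametes(pop, parent))
}

#' Biparental cross
#'
#' Each progeny receives one independent gamete from each parent; pedigree
#' is recorded.
#'
#' @param pop a `saf_pop` containing both parents.
#' @param p1,p2 parent index or id.
#' @param n_progeny number of progeny (>= 1).
#' @param generation generation label for the progeny.
#' @param id_prefix prefix for autogenerated progeny ids.
#' @return a `saf_pop` of the progeny.
#' @export
cross <- function(pop, p1, p2, n_progeny, generation = "F1",
                  id_prefix = "X") {
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  make_crosses(pop, matrix(c(p1, p2), 1, 2), n_progeny, generation, id_prefix)
}

#' Execute a crossing plan
#'
#' @param pop a `saf_pop` with all parents.
#' @param plan two-column matrix of parent indices or ids, one row per cross.
#' @param n_progeny_per_cross progeny per cross.
#' @inheritParams cross
#' @return a `saf_pop` of all progeny, ordered by cross then progeny; the
#'   originating cross of each progeny is in attribute `cross_id`.
#' @export
make_crosses <- function(pop, plan, n_progeny_per_cross, generation = "F1",
                         id_prefix = "X") {
  if (is.character(plan)) {
    plan <- matrix(match(plan, pop$id), ncol = 2)
  }
  plan <- as.matrix(plan)
  if (anyNA(plan)) stop("unknown parent in crossing plan")
  nc <- nrow(plan)
  k <- n_progeny_per_cross
  p1 <- rep(plan[, 1], each = k)
  p2 <- rep(plan[, 2], each = k)
  g1 <- make_gametes(pop, p1)
  g2 <- make_gametes(pop, p2)
  haplo <- matrix(0L, 2L * nc * k, ncol(g1))
  haplo[seq(1, 2 * nc * k, by = 2), ] <- g1
  haplo[seq(2, 2 * nc * k, by = 2), ] <- g2
  id <- paste0(id_prefix, rep(seq_len(nc), each = k), "_", rep(seq_len(k), nc))
  parents <- cbind(pop$id[p1], pop$id[p2])
  out <- new_population(haplo, pop$map, id, parents, generation)
  attr(out, "cross_id") <- rep(seq_len(nc), each = k)
  out
}

# self a set of individuals once, one progeny each
self_once <- function(pop, idx = seq_len(n_ind(pop)), generation,
                      id_prefix = "S") {
  g1 <- make_gametes(pop, idx)
  g2 <- make_gametes(pop, idx)
  n <- length(idx)
  haplo <- matrix(0L, 2L * n, ncol(g1))
  haplo[seq(1, 2 * n, by = 2), ] <- g1
  haplo[seq(2, 2 * n, by = 2), ] <- g2
  id <- paste0(id_prefix, seq_len(n))
  out <- new_population(haplo, pop$map, id,
                        cbind(pop$id[idx], pop$id[idx]), generation)
  out
}

#' Advance F1 families to F4 by single-seed descent
#'
#' Per cross: the kept F1s are selfed round-robin to produce an F2 bulk of
#' `n_f2_bulk` plants; `n_f4_per_cross` F2 plants are sampled from the bulk
#' (without replacement) as lineage founders; each lineage is selfed
#' F2 -> F3 -> F4 keeping a single seed per generation.
#'
#' @param f1s a `saf_pop` of F1 individuals carrying a `cross_id` attribute
#'   (as produced by [make_crosses()]), or with `cross_id` passed explicitly.
#' @param n_f2_bulk F2 bulk size per cross.
#' @param n_f4_per_cross number of F4 individuals returned per cross.
#' @param cross_id integer cross membership per F1 (defaults to the
#'   attribute on `f1s`).
#' @param id_prefix prefix for generated ids.
#' @return a `saf_pop` of `n_f4_per_cross` F4 individuals per cross, with a
#'   `cross_id` attribute.
#' @export
advance_ssd <- function(f1s, n_f2_bulk = 200, n_f4_per_cross = 100,
                        cross_id = attr(f1s, "cross_id"),
                        id_prefix = "F4_") {
  if (is.null(cross_id)) stop("cross membership of the F1s is required")
  if (n_ind(f1s) < 1) stop("at least one F1 per cross is required")
  stopifnot(length(cross_id) == n_ind(f1s))
  if (n_f4_per_cross > n_f2_bulk)
    stop("cannot sample more SSD lineages than the F2 bulk size")
  crosses <- sort(unique(cross_id))
  # F2 bulk: self the F1s of each cross round-robin
  f2_parents <- unlist(lapply(crosses, function(cc) {
    i <- which(cross_id == cc)
    rep_len(i, n_f2_bulk)
  }))
  f2 <- self_once(f1s, f2_parents, "F2", paste0(id_prefix, "f2_"))
  # sample lineage founders from each bulk
  keep <- unlist(lapply(seq_along(crosses), function(ci) {
    (ci - 1L) * n_f2_bulk + sample.int(n_f2_bulk, n_f4_per_cross)
  }))
  f3 <- self_once(f2, keep, "F3", paste0(id_prefix, "f3_"))
  f4 <- self_once(f3, seq_len(n_ind(f3)), "F4", id_prefix)
  attr(f4, "cross_id") <- rep(crosses, each = n_f4_per_cross)
  f4
}

#' Mean marker heterozygosity per individual
#' @param pop a `saf_pop`.
#' @return numeric vector, fraction of heterozygous markers per individual.
#' @export
heterozygosity <- function(pop) {
  d <- dosages(pop)
  rowMeans(d == 1L)
}
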