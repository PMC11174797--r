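#' Export / import genotype dosages as CSV
#'
#' Plain dosage matrix (individuals x markers) with an `id` column and a
#' header row of marker ids; reads back losslessly.
#'
#' @param pop a `saf_pop` (or a dosage matrix with dimnames).
#' @param path file path.
#' @export
export_dosages_csv <- function(pop, path) {
  d <- if (inherits(pop, "saf_pop")) dosages(pop) else pop
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_dosages_csv
#' @export
import_dosages_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Export phenotypes as CSV (id, GY, OL)
#' @param phen phenotype data.frame from [simulate_phenotypes()].
#' @param path file path.
#' @export
export_phenotypes_csv <- function(phen, path) {
  write.csv(phen, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_phenotypes_csv
#' @export
import_phenotypes_csv <- function(path) read.csv(path)

#' Export a genetic map as 3-column TSV (marker, chromosome, position_Morgans)
#' @param map a `saf_map`.
#' @param path file path.
#' @export
export_map_tsv <- function(map, path) {
  write.table(data.frame(marker = map$marker_ids, chromosome = map$chr,
                         position_Morgans = map$pos),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_map_tsv
#' @param lengths per-chromosome lengths in Morgans; defaults to the largest
#'   observed position per chromosome.
#' @export
import_map_tsv <- function(path, lengths = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (is.null(lengths))
    lengths <- vapply(split(df$position_Morgans, df$chromosome), max, 1)
  genetic_map(chr = df$chromosome, pos = df$position_Morgans,
              lengths = lengths, marker_ids = df$marker)
}

#' Export a pedigree as CSV (id, parent1, parent2, generation)
#' @param pop a `saf_pop`.
#' @param path file path.
#' @export
export_pedigree_csv <- function(pop, path) {
  write.csv(data.frame(id = pop$id, parent1 = pop$parents[, 1],
                       parent2 = pop$parents[, 2],
                       generation = pop$generation),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a crossing plan as CSV (cross_id, parent1, parent2, pair_fitness)
#' @param plan a `cross_plan`.
#' @param path file path.
#' @export
export_cross_plan_csv <- function(plan, path) {
  pf <- if (is.null(plan$pair_fitness)) NA_real_ else plan$pair_fitness
  write.csv(data.frame(cross_id = seq_len(nrow(plan$crosses)),
                       parent1 = plan$crosses[, 1],
                       parent2 = plan$crosses[, 2],
                       pair_fitness = pf),
            path, row.names = FALSE)
  invisible(path)
}

#' Export simulation records as tidy CSV
#'
#' One row per (replicate, cycle, trait): strategy, mean and SD of selected
#' parents' GEBVs, and inbreeding coefficient F.
#'
#' @param result a `sim_result`.
#' @param path file path.
#' @export
export_records_csv <- function(result, path) {
  rec <- result$records
  long <- do.call(rbind, lapply(c("GY", "OL"), function(tr) {
    data.frame(replicate = rec$replicate, cycle = rec$cycle,
               strategy = rec$strategy, trait = tr,
               mean_gebv = rec[[paste0("mean_gebv_", tr)]],
               sd_gebv = rec[[paste0("sd_gebv_", tr)]], F = rec$F)
  }))
  long <- long[order(long$replicate, long$cycle, long$trait), ]
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Export a population as a phased VCF
#'
#' Minimal VCFv4.2 with a phased GT field ("|" separator); marker positions
#' are the map positions in centiMorgans rounded to integer base-pair
#' surrogates (1 cM = 10 kb) purely so records are valid and ordered.
#'
#' @param pop a `saf_pop`.
#' @param path file path (plain-text `.vcf`).
#' @export
export_vcf <- function(pop, path) {
  map <- pop$map
  n <- n_ind(pop)
  h1 <- pop$haplo[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- pop$haplo[seq(2, 2 * n, 2), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=safsim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", pop$id), collapse = "\t")), con)
  pos_bp <- round(map$pos * 1e6) + 1
  for (j in seq_along(map$pos)) {
    gt <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(paste0("chr", map$chr[j]), pos_bp[j],
                       map$marker_ids[j], "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Import founders from a VCF
#'
#' Reads GT fields from a plain-text VCF. Unphased heterozygotes ("0/1")
#' are phased uniformly at random (meiosis needs phase; real panels are
#' typically unphased).
#'
#' @param path VCF file path.
#' @param map optional `saf_map`; defaults to the safflower layout
#'   ([genetic_map()] with 12 chromosomes) over the file's markers.
#' @return a `saf_pop`.
#' @export
import_vcf <- function(path, map = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  ids <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  m <- length(rows)
  n <- length(ids)
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  marker_ids <- character(m)
  for (j in seq_len(m)) {
    f <- rows[[j]]
    marker_ids[j] <- f[3]
    gt <- substr(f[-(1:9)], 1, 3)
    a1 <- as.integer(substr(gt, 1, 1))
    a2 <- as.integer(substr(gt, 3, 3))
    unphased <- substr(gt, 2, 2) == "/" & a1 != a2
    flip <- unphased & (runif(n) < 0.5)
    tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
    h1[, j] <- a1
    h2[, j] <- a2
  }
  if (is.null(map)) map <- genetic_map(m, marker_ids = marker_ids)
  haplo <- matrix(0L, 2L * n, m)
  haplo[seq(1, 2 * n, 2), ] <- h1
  haplo[seq(2, 2 * n, 2), ] <- h2
  new_population(haplo, map, id = ids, generation = "founder")
}
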