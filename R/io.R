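# Tab-separated interchange formats: summary statistics (consumed by the
# PRS stage) and wide per-pair twin tables (consumed by the twin model).

.sumstat_cols <- c("snp_id", "beta_main", "se_main", "z_main", "p_main",
                   "beta_mod", "se_mod", "beta_int", "se_int", "z_int",
                   "p_int", "n")

#' Write and read GWAS summary statistics as TSV
#'
#' A fixed column order (`snp_id`, main-effect estimate/SE/z/p, moderator
#' estimate/SE, interaction estimate/SE/z/p, `n`) keeps score construction
#' file-driven; the scan kind is recorded in a leading `#` comment so the
#' file is self-describing. Standard-scan files carry `NA` in the
#' interaction columns.
#'
#' @param scan a [gwas_scan()] result.
#' @param path file path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns a `gwas_scan`-classed data.frame.
#' @export
write_sumstats <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scan: ", attr(scan, "scan")), con)
  write.table(as.data.frame(scan)[, .sumstat_cols], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^# scan:\\s*", "", first)
  if (!kind %in% c("moderated", "standard"))
    stop("missing or unrecognised scan-kind header in ", path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  d$degenerate <- is.na(d$beta_main)
  structure(d, scan = kind, n = d$n[1], class = c("gwas_scan", "data.frame"))
}

#' Write and read wide per-pair twin tables as TSV
#'
#' Columns `pair_id`, `zygosity`, `m1`, `m2`, `y1`, `y2` — the layout
#' [ace_gxe()] consumes.
#'
#' @param pairs data.frame from [twin_pairs()].
#' @param path file path.
#' @export
write_twin_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_twin_pairs
#' @export
read_twin_pairs <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a simulated twin dataset to tab-separated files
#'
#' Emits one genotype matrix file per stored role
#' (`genotypes_<zygosity>_<role>.tsv`, rows = individuals, columns = SNP
#' ids) and a long `phenotypes.tsv` with columns `family_id`, `zygosity`,
#' `role`, `moderator`, `phenotype` covering every role.
#'
#' @param data a `twin_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_twin_dataset <- function(data, dir) {
  stopifnot(inherits(data, "twin_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (z in c("mz", "dz")) {
    grp <- data[[z]]
    for (r in names(grp$phenotype)) {
      g <- grp$genotype[[r]]
      if (!is.null(g))
        write.table(g, file.path(dir, sprintf("genotypes_%s_%s.tsv", z, r)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      mod <- grp$moderator[[r]]
      rows[[paste(z, r)]] <- data.frame(
        family_id = paste0(z, seq_len(grp$n)), zygosity = toupper(z),
        role = r,
        moderator = if (is.null(mod)) NA_real_ else mod,
        phenotype = grp$phenotype[[r]])
    }
  }
  write.table(do.call(rbind, rows), file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Save and restore a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
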