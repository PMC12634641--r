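#' Configuration for the twin-family GxE simulator
#'
#' Collects every knob of the generative model: a phenotype built from a
#' moderated regression, `Y = b0 + G b1 + b2 m + (G * m) b3 + e`, on top of
#' biometrically faithful twin-family genotypes (parental allele draws with
#' Mendelian transmission, so MZ co-twins correlate 1 and DZ co-twins 0.5 at
#' every SNP).
#'
#' @param n_mz,n_dz number of MZ / DZ twin families.
#' @param n_snps number of independent biallelic SNPs.
#' @param maf minor-allele frequency shared by all SNPs. The default 0.5
#'   makes a single SNP with unit effect contribute variance `2pq = 0.5`,
#'   i.e. half the phenotypic variance when `residual_variance = 0.5`.
#' @param effect_regime `"fixed"` (every SNP gets the same coefficient,
#'   `sqrt(scale / n_snps)`) or `"normal"` (coefficients drawn from
#'   `N(0, scale / n_snps)`).
#' @param total_main_variance,total_int_variance targets for the summed
#'   squared main-effect and interaction coefficients. Set
#'   `total_int_variance = 0` for a no-interaction model.
#' @param moderator_kind `"binary"` (Bernoulli) or `"continuous"` (standard
#'   normal) environmental moderator, drawn independently per twin.
#' @param moderator_prevalence probability of the exposed level for a binary
#'   moderator.
#' @param beta0,beta2 intercept and moderator main effect (both 0 by
#'   default; the moderator then acts purely through the interaction).
#' @param residual_variance variance of the Gaussian residual.
#' @param seed optional integer master seed. Each stage of the generator
#'   (effects, moderators, genotypes, residuals) is re-seeded from it, so
#'   datasets are bit-reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_twin_data()], [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_mz = 100, n_dz = 100, n_snps = 5, seed = 1)
#' cfg
sim_config <- function(n_mz = 100000, n_dz = 100000, n_snps = 1, maf = 0.5,
                       effect_regime = c("fixed", "normal"),
                       total_main_variance = 1, total_int_variance = 1,
                       moderator_kind = c("binary", "continuous"),
                       moderator_prevalence = 0.5,
                       beta0 = 0, beta2 = 0,
                       residual_variance = 0.5, seed = NULL) {
  effect_regime <- match.arg(effect_regime)
  moderator_kind <- match.arg(moderator_kind)
  if (n_mz < 1 || n_dz < 1) stop("need at least one family per zygosity")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (maf <= 0 || maf >= 1) stop("maf must lie strictly in (0, 1)")
  if (residual_variance <= 0) stop("residual_variance must be positive")
  if (total_main_variance < 0 || total_int_variance < 0)
    stop("variance scales must be non-negative")
  if (moderator_kind == "binary" &&
      (moderator_prevalence <= 0 || moderator_prevalence >= 1))
    stop("moderator_prevalence must lie strictly in (0, 1)")
  structure(list(
    n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
    n_snps = as.integer(n_snps), maf = maf,
    effect_regime = effect_regime,
    total_main_variance = total_main_variance,
    total_int_variance = total_int_variance,
    moderator_kind = moderator_kind,
    moderator_prevalence = moderator_prevalence,
    beta0 = beta0, beta2 = beta2,
    residual_variance = residual_variance,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Twin GxE simulation configuration\n")
  cat(sprintf("  families: %d MZ + %d DZ; %d SNP(s), maf %.3g\n",
              x$n_mz, x$n_dz, x$n_snps, x$maf))
  cat(sprintf("  effects: %s regime, sum(b1^2) = %.3g, sum(b3^2) = %.3g\n",
              x$effect_regime, x$total_main_variance, x$total_int_variance))
  cat(sprintf("  moderator: %s (prevalence %.2f); residual variance %.3g\n",
              x$moderator_kind, x$moderator_prevalence, x$residual_variance))
  invisible(x)
}

#' Draw per-SNP main and interaction effect sizes
#'
#' Under the fixed regime every SNP receives the same coefficient,
#' `sqrt(total_variance / n_snps)`, so the summed squared effects hit the
#' target exactly (0.0316 per SNP at 1000 SNPs and unit total variance).
#' Under the normal regime coefficients are drawn independently from
#' `N(0, total_variance / n_snps)`, giving a sign-mixed architecture whose
#' summed squared effects hit the target in expectation.
#'
#' @param config a [sim_config()].
#' @return An object of class `effect_sizes`: list with `beta0`, `beta1`
#'   (length `n_snps`), `beta2`, `beta3` (length `n_snps`) and the regime.
#' @export
draw_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_snps
  one <- function(scale) {
    if (scale == 0) return(rep(0, k))
    if (config$effect_regime == "fixed") rep(sqrt(scale / k), k)
    else rnorm(k, 0, sqrt(scale / k))
  }
  structure(list(
    beta0 = config$beta0,
    beta1 = one(config$total_main_variance),
    beta2 = config$beta2,
    beta3 = one(config$total_int_variance),
    regime = config$effect_regime
  ), class = "effect_sizes")
}

#' Simulate parental genotypes with retained allele draws
#'
#' Each parent receives two Bernoulli(`maf`) alleles per SNP; the genotype is
#' their sum, i.e. Binomial(2, maf) counts in 0/1/2. The individual allele
#' draws are retained so that [transmit_genotypes()] can resample them to
#' build offspring.
#'
#' @param n_families number of families.
#' @param n_snps number of SNPs.
#' @param maf allele frequency in (0, 1); the degenerate edges are rejected
#'   by [sim_config()], but 0/1 are tolerated here for boundary checks.
#' @return list with components `mother` and `father`, each holding integer
#'   matrices `a1`, `a2` (allele draws) and `genotype` (their sum), all
#'   `n_families x n_snps`.
#' @export
simulate_parents <- function(n_families, n_snps, maf) {
  if (maf < 0 || maf > 1) stop("maf must lie in [0, 1]")
  draw <- function() {
    matrix(rbinom(n_families * n_snps, 1L, maf), n_families, n_snps)
  }
  one_parent <- function() {
    a1 <- draw(); a2 <- draw()
    list(a1 = a1, a2 = a2, genotype = a1 + a2)
  }
  list(mother = one_parent(), father = one_parent())
}

#' Transmit parental alleles to a twin pair
#'
#' For DZ twins each twin independently receives one randomly chosen
#' maternal and one paternal allele, which yields an expected genotype
#' correlation of 0.5 across co-twins. For MZ twins a single transmission
#' draw is shared, so co-twin genotypes are identical.
#'
#' @param parents output of [simulate_parents()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return list of integer genotype matrices `twin1`, `twin2`.
#' @export
transmit_genotypes <- function(parents, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  m <- parents$mother; f <- parents$father
  n <- nrow(m$a1); k <- ncol(m$a1)
  pick <- function(p) {
    sel <- matrix(rbinom(n * k, 1L, 0.5), n, k)
    p$a1 * (1L - sel) + p$a2 * sel
  }
  if (zygosity == "MZ") {
    g <- pick(m) + pick(f)
    list(twin1 = g, twin2 = g)
  } else {
    list(twin1 = pick(m) + pick(f), twin2 = pick(m) + pick(f))
  }
}

#' Construct phenotypes from the moderated-regression model
#'
#' `Y = b0 + G b1 + b2 m + (G * m) b3 + e` with Gaussian residuals. When
#' `moderator` is `NULL` (parents in the study presets) the moderator and
#' interaction terms are dropped.
#'
#' @param genotypes numeric/integer matrix, individuals by SNPs.
#' @param moderator moderator vector (length `nrow(genotypes)`) or `NULL`.
#' @param effects an `effect_sizes` object from [draw_effects()].
#' @param residual_variance residual variance of `e`.
#' @return list with `phenotype` and the drawn `residual` vector (kept so
#'   the deterministic part of the construction can be verified exactly).
#' @export
simulate_phenotype <- function(genotypes, moderator, effects,
                               residual_variance = 0.5) {
  n <- nrow(genotypes)
  if (ncol(genotypes) != length(effects$beta1))
    stop("genotype columns do not match effect-size length")
  if (!is.null(moderator) && length(moderator) != n)
    stop("moderator length does not match genotype rows")
  gmain <- drop(genotypes %*% effects$beta1)
  eta <- effects$beta0 + gmain
  if (!is.null(moderator)) {
    gint <- drop(genotypes %*% effects$beta3)
    eta <- eta + effects$beta2 * moderator + moderator * gint
  }
  residual <- rnorm(n, 0, sqrt(residual_variance))
  list(phenotype = eta + residual, residual = residual)
}

# Roles a caller can ask simulate_twin_data() to retain genotypes for.
.twin_roles <- c("twin1", "twin2", "mother", "father")
.keep_all <- as.vector(outer(c("mz", "dz"), .twin_roles, paste, sep = "_"))

# Generate one zygosity group chunk-by-chunk. Genotype matrices are only
# materialised for kept roles, but the RNG draw sequence never depends on
# `keep`, so a dataset is reproducible regardless of what is stored.
.simulate_zygosity <- function(zyg, n, config, effects, moderator, keep) {
  k <- config$n_snps
  chunk <- 250L
  starts <- seq(1L, k, by = chunk)
  kept <- .twin_roles[paste(tolower(zyg), .twin_roles, sep = "_") %in% keep]
  store <- setNames(vector("list", length(kept)), kept)
  for (r in kept) store[[r]] <- matrix(0L, n, k)
  gmain <- setNames(rep(list(numeric(n)), 4L), .twin_roles)
  gint <- list(twin1 = numeric(n), twin2 = numeric(n))
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, k)
    parents <- simulate_parents(n, length(idx), config$maf)
    twins <- transmit_genotypes(parents, zyg)
    block <- list(twin1 = twins$twin1, twin2 = twins$twin2,
                  mother = parents$mother$genotype,
                  father = parents$father$genotype)
    b1 <- effects$beta1[idx]; b3 <- effects$beta3[idx]
    for (r in .twin_roles) {
      gmain[[r]] <- gmain[[r]] + drop(block[[r]] %*% b1)
      if (r %in% c("twin1", "twin2"))
        gint[[r]] <- gint[[r]] + drop(block[[r]] %*% b3)
      if (r %in% kept) store[[r]][, idx] <- block[[r]]
    }
  }
  snp_ids <- sprintf("snp%04d", seq_len(k))
  for (r in kept) colnames(store[[r]]) <- snp_ids
  phenotype <- residual <- setNames(vector("list", 4L), .twin_roles)
  sdr <- sqrt(config$residual_variance)
  for (r in .twin_roles) {
    eps <- rnorm(n, 0, sdr)
    eta <- effects$beta0 + gmain[[r]]
    if (r %in% c("twin1", "twin2"))
      eta <- eta + effects$beta2 * moderator[[r]] + moderator[[r]] * gint[[r]]
    phenotype[[r]] <- eta + eps
    residual[[r]] <- eps
  }
  list(n = n,
       genotype = list(twin1 = store[["twin1"]], twin2 = store[["twin2"]],
                       mother = store[["mother"]], father = store[["father"]]),
       moderator = moderator, phenotype = phenotype, residual = residual)
}

#' Simulate a complete twin-family GxE dataset
#'
#' Runs the full generator: effect sizes, parental alleles, Mendelian
#' transmission to MZ and DZ twin pairs, per-twin environmental moderators,
#' and moderated-regression phenotypes for twins and (moderator-free)
#' parents. Genotypes are generated in SNP chunks so genome-scale
#' configurations (1e5 families x 1000 SNPs) stay within ordinary memory;
#' only the roles named in `keep` retain their genotype matrices.
#'
#' @param config a [sim_config()].
#' @param keep character vector of roles whose genotype matrices to store,
#'   from `"mz_twin1"`, `"mz_twin2"`, `"mz_mother"`, `"mz_father"` and the
#'   `dz_*` equivalents. Defaults to all roles. Phenotypes, moderators and
#'   residuals are always stored for every role.
#' @return An object of class `twin_dataset`: list with `config`, `effects`
#'   and per-zygosity components `mz`, `dz`, each holding `genotype`,
#'   `moderator`, `phenotype` and `residual` lists keyed by role.
#' @export
#' @examples
#' d <- simulate_twin_data(sim_config(n_mz = 200, n_dz = 200, seed = 7))
#' cor(d$dz$genotype$twin1[, 1], d$dz$genotype$twin2[, 1])
simulate_twin_data <- function(config, keep = .keep_all) {
  stopifnot(inherits(config, "sim_config"))
  keep <- match.arg(keep, .keep_all, several.ok = TRUE)
  seed <- config$seed
  stage <- function(k) if (!is.null(seed)) set.seed(derive_seed(seed, k))

  stage(1L)
  effects <- draw_effects(config)

  draw_mod <- function(n) {
    if (config$moderator_kind == "binary")
      rbinom(n, 1L, config$moderator_prevalence)
    else rnorm(n)
  }
  stage(2L)
  mz_mod <- list(twin1 = draw_mod(config$n_mz), twin2 = draw_mod(config$n_mz))
  stage(3L)
  dz_mod <- list(twin1 = draw_mod(config$n_dz), twin2 = draw_mod(config$n_dz))

  stage(4L)
  mz <- .simulate_zygosity("MZ", config$n_mz, config, effects, mz_mod, keep)
  stage(5L)
  dz <- .simulate_zygosity("DZ", config$n_dz, config, effects, dz_mod, keep)

  structure(list(config = config, effects = effects, mz = mz, dz = dz),
            class = "twin_dataset")
}

#' @export
print.twin_dataset <- function(x, ...) {
  cat("Simulated twin-family GxE dataset\n")
  cat(sprintf("  %d MZ + %d DZ families, %d SNP(s)\n",
              x$mz$n, x$dz$n, x$config$n_snps))
  kept <- unlist(lapply(c("mz", "dz"), function(z) {
    r <- names(Filter(Negate(is.null), x[[z]]$genotype))
    if (length(r)) paste(z, unique(r), sep = "_") else character()
  }))
  cat("  genotypes stored for:", paste(unique(kept), collapse = ", "), "\n")
  cat(sprintf("  effect regime: %s; sum(b1^2) = %.4g, sum(b3^2) = %.4g\n",
              x$effects$regime, sum(x$effects$beta1^2), sum(x$effects$beta3^2)))
  invisible(x)
}

#' Simulate one of the four preset studies
#'
#' Presets follow the simulation-study designs: Study 1 is a single SNP with
#' unit main effect and no interaction; Study 2 adds a unit interaction with
#' a binary moderator; Study 3 spreads the same total main and interaction
#' variance over 1000 SNPs with equal coefficients (0.0316 each); Study 4
#' draws the 1000 coefficients from centred normal distributions with the
#' same total variance, so interaction signs mix. All presets use maf 0.5, a
#' Bernoulli(0.5) moderator and residual variance 0.5.
#'
#' @param study integer 1-4.
#' @param n_mz,n_dz family counts; default 100,000 each for the single-SNP
#'   studies and 5,000 MZ / 100,000 DZ for the polygenic ones (families are
#'   iid, so a smaller MZ set equals taking the first families of a larger
#'   one).
#' @param seed master seed (see [sim_config()]).
#' @param keep genotype roles to store; defaults to all roles for single-SNP
#'   studies and to the analysis roles (`dz_twin1`, `mz_twin1`)
#'   for the polygenic ones.
#' @param ... further overrides passed to [sim_config()].
#' @return A `twin_dataset` whose `config` carries a `study` attribute.
#' @export
simulate_study <- function(study, n_mz = NULL, n_dz = NULL, seed = NULL,
                           keep = NULL, ...) {
  if (!study %in% 1:4) stop("unknown study id: ", study)
  preset <- switch(study,
    list(n_snps = 1L, effect_regime = "fixed", total_int_variance = 0),
    list(n_snps = 1L, effect_regime = "fixed"),
    list(n_snps = 1000L, effect_regime = "fixed"),
    list(n_snps = 1000L, effect_regime = "normal"))
  if (is.null(n_mz)) n_mz <- if (preset$n_snps == 1L) 100000L else 5000L
  if (is.null(n_dz)) n_dz <- 100000L
  args <- utils::modifyList(
    c(list(n_mz = n_mz, n_dz = n_dz, seed = seed), preset), list(...))
  config <- do.call(sim_config, args)
  attr(config, "study") <- study
  if (is.null(keep)) {
    keep <- if (config$n_snps == 1L) .keep_all
            else c("dz_twin1", "mz_twin1")
  }
  simulate_twin_data(config, keep = keep)
}

#' Extract twin pairs for variance-components modelling
#'
#' Returns the wide per-pair layout the twin model consumes: one row per
#' pair with both twins' moderators and phenotypes.
#'
#' @param data a `twin_dataset`.
#' @param n_pairs pairs taken from the start of each zygosity group (the
#'   twin analyses use the first 2000 MZ and 2000 DZ pairs by default).
#' @param zygosity which groups to include.
#' @return data.frame with columns `pair_id`, `zygosity`, `m1`, `m2`, `y1`,
#'   `y2`.
#' @export
twin_pairs <- function(data, n_pairs = 2000, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(data, "twin_dataset"))
  zygosity <- match.arg(zygosity, several.ok = TRUE)
  out <- lapply(zygosity, function(z) {
    g <- data[[tolower(z)]]
    if (g$n < n_pairs)
      stop(sprintf("only %d %s pairs available (asked for %d)", g$n, z, n_pairs))
    i <- seq_len(n_pairs)
    data.frame(pair_id = paste0(tolower(z), i), zygosity = z,
               m1 = g$moderator$twin1[i], m2 = g$moderator$twin2[i],
               y1 = g$phenotype$twin1[i], y2 = g$phenotype$twin2[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
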