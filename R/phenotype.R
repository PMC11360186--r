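## Multiallelic trait model: each QTL assigns one additive effect (days)
## per founder allele; heterozygotes get the mean of their two founder
## effects; environments add fixed offsets.

#' Define a trait model
#'
#' @param chrom,pos parallel vectors of QTL coordinates.
#' @param effects QTL x founder matrix of additive allele effects (days).
#' @param env_effects per-environment offsets (days); length = number of
#'   environments.
#' @param residual_sd residual standard deviation (days), > 0 unless
#'   exactly 0 is wanted for noiseless checks.
#' @param baseline intercept (days).
#' @return a \code{trait_model}.
#' @export
trait_model <- function(chrom, pos, effects, env_effects = c(0, 0),
                        residual_sd = 3, baseline = 80) {
  effects <- as.matrix(effects)
  if (length(chrom) != length(pos) || nrow(effects) != length(pos))
    stop("chrom, pos and rows of effects must agree")
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  structure(list(chrom = chrom, pos = pos, effects = effects,
                 env_effects = env_effects, residual_sd = residual_sd,
                 baseline = baseline),
            class = "trait_model")
}

#' Genetic values of simulated lines under a trait model
#'
#' @param mosaics list of \code{mosaic} objects.
#' @param trait a \code{trait_model}.
#' @param panel a \code{founder_panel} (for coordinate validation).
#' @return numeric vector, one genetic value (days, no env/noise) per line.
#' @export
genetic_values <- function(mosaics, trait, panel) {
  for (q in seq_along(trait$pos)) {
    if (!trait$chrom[q] %in% names(panel$chrom_lengths) ||
        trait$pos[q] < 1 ||
        trait$pos[q] > panel$chrom_lengths[[trait$chrom[q]]])
      stop("QTL off the simulated genome")
  }
  vapply(mosaics, function(m) {
    g <- trait$baseline
    for (q in seq_along(trait$pos)) {
      f1 <- founder_at(m$haps[[1]][[trait$chrom[q]]], trait$pos[q])
      f2 <- founder_at(m$haps[[2]][[trait$chrom[q]]], trait$pos[q])
      g <- g + (trait$effects[q, f1] + trait$effects[q, f2]) / 2
    }
    g
  }, 0)
}

#' Simulate phenotypes in several environments
#'
#' y = baseline + sum of QTL allele effects (heterozygotes get the mean of
#' the two founder effects) + environment offset + N(0, residual_sd^2).
#'
#' @inheritParams genetic_values
#' @param seed optional RNG seed.
#' @return data.frame with columns line, env, value (long format).
#' @export
simulate_phenotypes <- function(mosaics, trait, panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gv <- genetic_values(mosaics, trait, panel)
  ids <- vapply(seq_along(mosaics), function(i) {
    id <- mosaics[[i]]$line_id
    if (is.na(id)) sprintf("MG%04d", i) else id
  }, "")
  n_env <- length(trait$env_effects)
  do.call(rbind, lapply(seq_len(n_env), function(e) {
    data.frame(line = ids, env = paste0("E", e),
               value = gv + trait$env_effects[e] +
                 rnorm(length(gv), 0, trait$residual_sd))
  }))
}

#' Per-line phenotype means across environments
#'
#' @param pheno long-format phenotype data.frame (line, env, value).
#' @param line_ids optional ordering of lines for the result.
#' @export
line_means <- function(pheno, line_ids = NULL) {
  m <- tapply(pheno$value, pheno$line, mean)
  if (!is.null(line_ids)) m <- m[line_ids]
  m
}
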