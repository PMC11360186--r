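## Founder allele-effect ranking at QTLs: group means, Duncan's multiple
## range test with letter display, effect-level classification, and
## broad-sense heritability.

#' Founder group means at a bin
#'
#' One-way decomposition of the phenotype by founder label: group sizes,
#' means, SDs, and the pooled within-group error variance (ANOVA MSE).
#'
#' @param labels per-line founder labels at the bin (integer, NA allowed).
#' @param phenotype per-line phenotype vector.
#' @param min_group_n groups below this size are flagged
#'   (\code{eligible = FALSE}) and excluded from letter assignment.
#' @param founder_ids optional founder names.
#' @return an \code{allele_groups} list: \code{table} (founder, n, mean,
#'   sd, eligible), \code{mse}, \code{df}.
#' @export
founder_group_means <- function(labels, phenotype, min_group_n = 10,
                                founder_ids = NULL) {
  ok <- !is.na(labels) & !is.na(phenotype)
  y <- phenotype[ok]; g <- labels[ok]
  gn <- tapply(y, g, length)
  if (sum(gn >= min_group_n) < 2)
    stop("need at least 2 founder groups with n >= ", min_group_n)
  gm <- tapply(y, g, mean)
  gsd <- tapply(y, g, sd)
  within_ss <- sum((y - gm[as.character(g)])^2)
  df <- length(y) - length(gn)
  tab <- data.frame(
    founder = as.integer(names(gn)),
    n = as.integer(gn), mean = as.numeric(gm), sd = as.numeric(gsd),
    eligible = as.integer(gn) >= min_group_n)
  if (!is.null(founder_ids)) tab$founder_id <- founder_ids[tab$founder]
  structure(list(table = tab, mse = within_ss / df, df = df),
            class = "allele_groups")
}

## Duncan least-significant range for a span of p means
.duncan_crit <- function(p_span, df, alpha, mse, n_h) {
  protect <- (1 - alpha)^(p_span - 1)
  qtukey(protect, p_span, df) * sqrt(mse / n_h)
}

#' Duncan's multiple range test with letter display
#'
#' Means are sorted in descending order; a pair separated by span p
#' differs significantly when its difference exceeds the least
#' significant range q(1 - (1-alpha)^(p-1); p, df) * sqrt(MSE / n_h),
#' with n_h the harmonic mean group size (unbalanced designs).  Letters
#' are assigned from maximal non-significant stretches, so two groups
#' share a letter iff their range test is non-significant.
#'
#' @param groups an \code{allele_groups}.
#' @param alpha per-comparison level (default 0.05).
#' @return a \code{duncan_result}: data.frame (founder, n, mean, letters)
#'   in descending mean order, attribute \code{alpha}.
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (groups$df <= 0) stop("error df must be positive")
  tab <- groups$table[groups$table$eligible, ]
  mse <- max(groups$mse, .Machine$double.eps)  # epsilon guard
  ord <- order(tab$mean, decreasing = TRUE)
  tab <- tab[ord, ]
  k <- nrow(tab)
  n_h <- k / sum(1 / tab$n)
  differs <- function(i, j) {  # i < j in sorted order
    span <- j - i + 1
    (tab$mean[i] - tab$mean[j]) >= .duncan_crit(span, groups$df, alpha,
                                                mse, n_h)
  }
  ## maximal non-significant stretches -> letters
  stretches <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !differs(i, j + 1)) j <- j + 1
    stretches[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && stretches[[j]][1] <= stretches[[i]][1] &&
          stretches[[j]][2] >= stretches[[i]][2] &&
          !identical(stretches[[i]], stretches[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  use <- unique(stretches[keep])
  letters_vec <- rep("", k)
  for (s in seq_along(use)) {
    rng <- use[[s]][1]:use[[s]][2]
    letters_vec[rng] <- paste0(letters_vec[rng], letters[s])
  }
  res <- data.frame(founder = tab$founder, n = tab$n, mean = tab$mean,
                    letters = letters_vec)
  if ("founder_id" %in% names(tab)) res$founder_id <- tab$founder_id
  structure(res, alpha = alpha, class = c("duncan_result", "data.frame"))
}

#' Classify allele effect levels from a Duncan letter display
#'
#' The number of effect levels is the number of distinct letters used by
#' the display (overlapping groups like "ab" collapse toward the smaller
#' count).  Levels are labelled by the rank of their means relative to
#' the smallest: "none" (smallest), then "weak", "intermediate", up to
#' "strong" (largest); a founder with several letters is assigned its
#' first (higher-mean) letter.
#'
#' @param duncan a \code{duncan_result}.
#' @return list with \code{n_levels}, \code{assignment} (data.frame
#'   founder, mean, letters, level, label).
#' @export
classify_effect_levels <- function(duncan) {
  letter_sets <- strsplit(duncan$letters, "")
  used <- sort(unique(unlist(letter_sets)))
  L <- length(used)
  labels <- if (L == 1) "none"
  else if (L == 2) c("strong", "none")
  else if (L == 3) c("strong", "weak", "none")
  else c("strong",
         rep("intermediate", L - 3), "weak", "none")
  ## letters were assigned in descending mean order: letter index = rank
  lev <- vapply(letter_sets, function(s) match(s[1], used), 0L)
  assignment <- data.frame(founder = duncan$founder, mean = duncan$mean,
                           letters = duncan$letters, level = lev,
                           label = labels[lev])
  list(n_levels = L, assignment = assignment)
}

#' Broad-sense heritability from multi-environment line means
#'
#' From the line x environment ANOVA with one observation per cell:
#' sigma2_G = (MS_line - MS_error) / r and sigma2_e = MS_error, with r
#' the number of environments; H2 = 100 * sigma2_G / (sigma2_G +
#' sigma2_e / r).  Negative variance estimates are floored at 0.
#'
#' @param pheno long-format data.frame with columns line, env, value.
#' @return list with \code{H2} (percent), \code{sigma2_G},
#'   \code{sigma2_e}.
#' @export
broad_sense_heritability <- function(pheno) {
  r <- length(unique(pheno$env))
  n_l <- length(unique(pheno$line))
  if (r < 2) stop("need at least 2 environments")
  if (n_l < 2) stop("need at least 2 lines")
  fit <- lm(value ~ factor(line) + factor(env), data = pheno)
  an <- anova(fit)
  ms_line <- an["factor(line)", "Mean Sq"]
  ms_err <- an["Residuals", "Mean Sq"]
  sigma2_g <- max((ms_line - ms_err) / r, 0)
  denom <- sigma2_g + ms_err / r
  list(H2 = if (denom == 0) 100 else 100 * sigma2_g / denom,
       sigma2_G = sigma2_g, sigma2_e = ms_err)
}
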