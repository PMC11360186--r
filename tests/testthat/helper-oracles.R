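## Independent oracles used across the suite.  These deliberately avoid
## the package's own computational paths: probabilities are assembled by
## direct arithmetic and exhaustive enumeration.

## -- exhaustive HMM path enumeration ---------------------------------------
## emission/transition arithmetic written out directly from the model
## definition (not via the package's emission/transition functions).
oracle_hmm <- function(obs, alleles, pos, params) {
  K <- nrow(alleles)
  M <- length(obs)
  emit <- function(o, a) {
    if (is.na(o)) return(1)
    if (o == 1L) return(params$e_het)
    if (o == 2 * a) return(1 - params$e_hom - params$e_het)
    params$e_hom
  }
  trans <- function(d, i, j) {
    th <- 1 - exp(-params$lambda_bp * d)
    if (i == j) 1 - th * (K - 1) / K else th / K
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  logp <- apply(paths, 1, function(pth) {
    l <- log(1 / K) + log(emit(obs[1], alleles[pth[1], 1]))
    if (M > 1) for (m in 2:M) {
      l <- l + log(trans(pos[m] - pos[m - 1], pth[m - 1], pth[m])) +
        log(emit(obs[m], alleles[pth[m], m]))
    }
    l
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  post <- vapply(seq_len(K), function(k)
    vapply(seq_len(M), function(m) sum(w[paths[, m] == k]), 0),
    numeric(M))
  list(path = as.integer(paths[which.max(logp), ]),
       post = matrix(post, M, K))
}

## -- single-locus Markov recursion for a gamete killer ---------------------
## Genotype classes (KK, KV, VV) through the funnel (all eight-way F1s are
## KV under the default funnel with carriers = one four-way side) and g
## selfing generations; selection s removes victim gametes of one sex in
## heterozygotes.  Returns the victim allele frequency.
oracle_killer_freq <- function(g, s, start = c(KK = 0, KV = 1, VV = 0)) {
  f <- start
  for (i in seq_len(g)) {
    pK_sel <- 0.5 / (0.5 + 0.5 * (1 - s))       # selected sex, het parent
    pV_sel <- 1 - pK_sel
    ## the other sex transmits Mendelianly (1/2, 1/2)
    KK <- f["KK"] + f["KV"] * pK_sel * 0.5
    KV <- f["KV"] * (pK_sel * 0.5 + pV_sel * 0.5)
    VV <- f["VV"] + f["KV"] * pV_sel * 0.5
    f <- c(KK = unname(KK), KV = unname(KV), VV = unname(VV))
  }
  unname(f["VV"] + f["KV"] / 2)
}

## -- direct Hudson FST recomputation on an emitted allele matrix ----------
oracle_fst <- function(panel) {
  gA <- panel$group == "A"
  num <- den <- 0
  for (mk in panel$markers) {
    for (j in seq_len(ncol(mk$alleles))) {
      x1 <- mk$alleles[gA, j]
      x2 <- mk$alleles[!gA, j]
      p1 <- mean(x1); p2 <- mean(x2)
      h1 <- p1 * (1 - p1) / (length(x1) - 1)
      h2 <- p2 * (1 - p2) / (length(x2) - 1)
      num <- num + (p1 - p2)^2 - h1 - h2
      den <- den + p1 * (1 - p2) + p2 * (1 - p1)
    }
  }
  num / den
}

## -- transitive-closure merging of significant SNPs ------------------------
oracle_clump <- function(pos, window_bp) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= window_bp
  grp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(grp[adj[i, ]]), 0)
    if (all(new == grp)) break
    grp <- new
  }
  grp
}

## -- studentized-range CDF by numerical integration ------------------------
## P(Q_{p,df} <= q), integrating the range probability over the scaled
## chi distribution of the pooled SD.
oracle_ptukey <- function(q, p, df) {
  inner <- function(s) {   # P(range of p std normals <= q*s)
    vapply(s, function(si) {
      f <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(p - 1)
      p * integrate(f, -8, 8, rel.tol = 1e-9)$value
    }, 0)
  }
  dens <- function(s) {    # density of sqrt(chi2_df / df)
    exp((df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2 + log(2))
  }
  integrate(function(s) inner(s) * dens(s), 1e-6, 10,
            rel.tol = 1e-8)$value
}

## textbook Duncan procedure driven by the integration-based CDF
oracle_duncan_letters <- function(means, n, mse, df, alpha = 0.05) {
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  n_h <- k / sum(1 / n)
  crit <- function(span) {
    target <- (1 - alpha)^(span - 1)
    q <- uniroot(function(x) oracle_ptukey(x, span, df) - target,
                 c(0.01, 50))$root
    q * sqrt(mse / n_h)
  }
  differs <- function(i, j) (m[i] - m[j]) >= crit(j - i + 1)
  stretches <- lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !differs(i, j + 1)) j <- j + 1
    c(i, j)
  })
  keep <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(k), function(j) {
      i != j && stretches[[j]][1] <= stretches[[i]][1] &&
        stretches[[j]][2] >= stretches[[i]][2] &&
        !identical(stretches[[i]], stretches[[j]])
    }, TRUE))
  }, TRUE)
  use <- unique(stretches[keep])
  lt <- rep("", k)
  for (s in seq_along(use)) {
    rng <- use[[s]][1]:use[[s]][2]
    lt[rng] <- paste0(lt[rng], letters[s])
  }
  out <- rep("", k)
  out[ord] <- lt
  out
}

## -- small shared simulation fixture --------------------------------------
small_population <- function(n_lines = 40, n_chrom = 1,
                             chrom_length = 5e6, density = 5e-4,
                             n_selfing = 6, seed = 42,
                             selection_loci = list()) {
  panel <- simulate_founders(n_chrom = n_chrom,
                             chrom_length = chrom_length,
                             marker_density = density, seed = seed)
  design <- crossing_design(n_lines = n_lines, n_selfing_gens = n_selfing)
  mosaics <- run_pedigree(panel, design, selection_loci,
                          seed = seed + 1)
  list(panel = panel, design = design, mosaics = mosaics)
}
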