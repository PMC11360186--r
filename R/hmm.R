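## Hidden Markov model founder-ancestry inference.
##
## Homozygous-state HMM: one hidden state per founder (K = 8 by default);
## residual heterozygosity of the inbred lines is absorbed by the e_het
## emission term.  Transitions follow a junction process of intensity
## lambda_bp per bp: over distance d, theta = 1 - exp(-lambda_bp * d) is
## the probability that the ancestry has "mixed", spread uniformly over
## all K states.

#' HMM parameters for ancestry inference
#'
#' @param K number of founder states.
#' @param e_hom probability of observing the opposite homozygote given the
#'   founder state.
#' @param e_het probability of observing a heterozygous call.
#' @param lambda_bp junction intensity per bp.
#' @param min_seg_bp minimum retained segment length; shorter decoded
#'   segments are merged into a neighbour (default 5000 bp, the scale of
#'   the smallest population bins).
#' @return an \code{hmm_params} list.
#' @export
hmm_params <- function(K = 8, e_hom = 0.005, e_het = 0.026,
                       lambda_bp = 3e-7, min_seg_bp = 5000) {
  if (e_hom < 0 || e_het < 0 || e_hom + e_het >= 1)
    stop("need e_hom, e_het >= 0 and e_hom + e_het < 1")
  if (lambda_bp <= 0) stop("lambda_bp must be > 0")
  if (min_seg_bp < 0) stop("min_seg_bp must be >= 0")
  structure(list(K = K, e_hom = e_hom, e_het = e_het,
                 lambda_bp = lambda_bp, min_seg_bp = min_seg_bp),
            class = "hmm_params")
}

#' Emission probabilities at one marker
#'
#' For founder state f carrying allele a: P(obs = 2a) = 1 - e_hom - e_het,
#' P(obs = het) = e_het, P(obs = 2(1-a)) = e_hom.  A missing observation
#' is uninformative (all ones).
#'
#' @param obs observed genotype in 0/1/2/NA.
#' @param founder_alleles length-K 0/1 vector of founder alleles.
#' @param params an \code{hmm_params}.
#' @return length-K probability vector.
#' @export
emission_probs <- function(obs, founder_alleles, params) {
  K <- length(founder_alleles)
  if (is.na(obs)) return(rep(1, K))
  if (obs == 1L) return(rep(params$e_het, K))
  match_p <- 1 - params$e_hom - params$e_het
  ifelse(founder_alleles == obs / 2, match_p, params$e_hom)
}

## markers x K emission matrix for one chromosome
.emission_matrix <- function(obs, alleles, params) {
  M <- length(obs)
  K <- nrow(alleles)
  match_p <- 1 - params$e_hom - params$e_het
  E <- matrix(1, nrow = M, ncol = K)
  for (k in seq_len(K)) {
    a <- alleles[k, ]
    E[, k] <- ifelse(is.na(obs), 1,
                     ifelse(obs == 1L, params$e_het,
                            ifelse(obs == 2 * a, match_p, params$e_hom)))
  }
  E
}

#' Between-marker transition matrix
#'
#' With theta = 1 - exp(-lambda_bp * d): off-diagonal entries theta / K,
#' diagonal 1 - theta (K - 1) / K.
#'
#' @param d_bp distance in bp (>= 0).
#' @param params an \code{hmm_params}.
#' @return K x K stochastic matrix.
#' @export
transition_matrix <- function(d_bp, params) {
  if (d_bp < 0) stop("distance must be >= 0")
  K <- params$K
  theta <- 1 - exp(-params$lambda_bp * d_bp)
  T <- matrix(theta / K, K, K)
  diag(T) <- 1 - theta * (K - 1) / K
  T
}

## per-interval (theta) vector for a position vector
.thetas <- function(pos, params) 1 - exp(-params$lambda_bp * diff(pos))

#' Viterbi decoding of founder ancestry along one chromosome
#'
#' Log-domain dynamic program; ties are broken toward the lower founder
#' index.  If every marker is missing the path is a single run of founder
#' 1 with attribute \code{uniform = TRUE}.
#'
#' @param obs observed genotypes (0/1/2/NA), sorted by position.
#' @param alleles K x M founder allele matrix for the same markers.
#' @param pos marker positions (bp, strictly increasing).
#' @param params an \code{hmm_params}.
#' @return integer state path (length M), attribute \code{uniform} when
#'   the chromosome was uninformative.
#' @export
viterbi <- function(obs, alleles, pos, params) {
  M <- length(obs)
  K <- nrow(alleles)
  if (M == 0) return(integer(0))
  if (all(is.na(obs))) {
    return(structure(rep(1L, M), uniform = TRUE))
  }
  logE <- log(.emission_matrix(obs, alleles, params))
  theta <- .thetas(pos, params)
  l_off <- log(theta / K)
  l_diag <- log(1 - theta * (K - 1) / K)
  delta <- -log(K) + logE[1, ]
  back <- matrix(0L, nrow = M, ncol = K)
  for (m in seq_len(M)[-1]) {
    lo <- l_off[m - 1]; ld <- l_diag[m - 1]
    o1 <- which.max(delta)              # top-1 (lowest index on ties)
    d2 <- delta; d2[o1] <- -Inf
    o2 <- which.max(d2)                 # top-2
    stay <- delta + ld
    best_other <- ifelse(seq_len(K) == o1, delta[o2] + lo, delta[o1] + lo)
    from_other <- ifelse(seq_len(K) == o1, o2, o1)
    take_stay <- stay >= best_other     # tie -> stay (deterministic)
    delta <- ifelse(take_stay, stay, best_other) + logE[m, ]
    back[m, ] <- ifelse(take_stay, seq_len(K), from_other)
  }
  path <- integer(M)
  path[M] <- which.max(delta)
  for (m in rev(seq_len(M - 1))) path[m] <- back[m + 1, path[m + 1]]
  path
}

#' Forward-backward posterior probabilities along one chromosome
#'
#' Scaled-domain forward-backward; each row of the result sums to 1.
#'
#' @inheritParams viterbi
#' @return M x K posterior matrix.
#' @export
forward_backward <- function(obs, alleles, pos, params) {
  M <- length(obs)
  K <- nrow(alleles)
  if (M == 0) return(matrix(numeric(0), 0, K))
  if (all(is.na(obs))) return(matrix(1 / K, M, K))
  E <- .emission_matrix(obs, alleles, params)
  theta <- .thetas(pos, params)
  alpha <- matrix(0, M, K)
  a <- E[1, ] / K
  alpha[1, ] <- a / sum(a)
  for (m in seq_len(M)[-1]) {
    th <- theta[m - 1]
    prev <- alpha[m - 1, ]
    a <- (th / K * sum(prev) + (1 - th) * prev) * E[m, ]
    alpha[m, ] <- a / sum(a)
  }
  beta <- matrix(0, M, K)
  beta[M, ] <- 1
  for (m in rev(seq_len(M - 1))) {
    th <- theta[m]
    nb <- beta[m + 1, ] * E[m + 1, ]
    b <- th / K * sum(nb) + (1 - th) * nb
    beta[m, ] <- b / sum(b)
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Convert a decoded state path into ancestry segments
#'
#' Maximal constant runs become segments; the boundary between two runs is
#' placed at the midpoint of the flanking marker interval (floor).  Runs
#' shorter than \code{params$min_seg_bp} are merged into the neighbour
#' with the higher flanking mean posterior, and segments re-abutted.
#'
#' @param path integer state path.
#' @param pos marker positions (bp).
#' @param chrom_length chromosome length in bp.
#' @param params an \code{hmm_params}.
#' @param posterior optional M x K posterior matrix used for the per-run
#'   mean posterior and merge preference.
#' @return data.frame with columns start, end, founder, mean_posterior.
#' @export
segments_from_path <- function(path, pos, chrom_length, params,
                               posterior = NULL) {
  if (length(path) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      founder = integer(0), mean_posterior = numeric(0)))
  r <- rle(path)
  k <- length(r$lengths)
  last <- cumsum(r$lengths)
  first <- c(1, head(last, -1) + 1)
  ends <- c(vapply(seq_len(k - 1), function(i)
    floor((pos[last[i]] + pos[first[i + 1]]) / 2), 0), chrom_length)
  starts <- c(1, head(ends, -1) + 1)
  mp <- if (is.null(posterior)) rep(NA_real_, k) else
    vapply(seq_len(k), function(i)
      mean(posterior[first[i]:last[i], r$values[i]]), 0)
  seg <- data.frame(start = starts, end = ends, founder = r$values,
                    mean_posterior = mp)
  ## merge short segments into the flanking neighbour with the higher
  ## mean posterior (or the longer neighbour when posteriors are absent)
  repeat {
    len <- seg$end - seg$start + 1
    short <- which(len < params$min_seg_bp)
    if (length(short) == 0 || nrow(seg) == 1) break
    i <- short[which.min(len[short])]
    left <- if (i > 1) i - 1 else NA
    right <- if (i < nrow(seg)) i + 1 else NA
    pick <- if (is.na(left)) right
    else if (is.na(right)) left
    else if (!is.null(posterior) && !anyNA(seg$mean_posterior[c(left, right)])) {
      if (seg$mean_posterior[left] >= seg$mean_posterior[right]) left else right
    } else if (len[left] >= len[right]) left else right
    if (pick < i) {
      seg$end[pick] <- seg$end[i]
    } else {
      seg$start[pick] <- seg$start[i]
    }
    seg <- seg[-i, , drop = FALSE]
    ## re-merge neighbours that now share a founder
    j <- which(diff(seg$founder) == 0 &
               seg$end[-nrow(seg)] + 1 == seg$start[-1])
    while (length(j)) {
      seg$end[j[1]] <- seg$end[j[1] + 1]
      seg$mean_posterior[j[1]] <-
        mean(seg$mean_posterior[c(j[1], j[1] + 1)])
      seg <- seg[-(j[1] + 1), , drop = FALSE]
      j <- which(diff(seg$founder) == 0 &
                 seg$end[-nrow(seg)] + 1 == seg$start[-1])
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Infer ancestry segments for every line
#'
#' Runs Viterbi decoding per line and chromosome; posteriors from
#' forward-backward are attached as per-segment means and used when
#' filtering short segments.
#'
#' @param geno a \code{geno_matrix} of offspring genotypes.
#' @param panel a \code{founder_panel}.
#' @param params an \code{hmm_params}.
#' @return data.frame with columns line, chrom, start, end, founder,
#'   mean_posterior; segments abut within each line and chromosome.
#' @export
infer_ancestry <- function(geno, panel, params = hmm_params()) {
  out <- list()
  for (c in panel$chrom_names) {
    sel <- geno$marker_chrom == c
    pos <- geno$marker_pos[sel]
    al <- panel$markers[[c]]$alleles
    for (i in seq_len(nrow(geno$G))) {
      obs <- geno$G[i, sel]
      path <- viterbi(obs, al, pos, params)
      post <- forward_backward(obs, al, pos, params)
      seg <- segments_from_path(path, pos, panel$chrom_lengths[[c]],
                                params, post)
      seg$line <- geno$line_ids[i]
      seg$chrom <- c
      out[[length(out) + 1]] <- seg
    }
  }
  res <- do.call(rbind, out)
  res[, c("line", "chrom", "start", "end", "founder", "mean_posterior")]
}

#' Re-estimate the junction intensity from decoded segments
#'
#' lambda = total junctions / total decoded length.  A zero-junction
#' decode is floored at \code{min_lambda} with a warning.
#'
#' @param segments data.frame as returned by \code{\link{infer_ancestry}}.
#' @param min_lambda lower floor for the estimate.
#' @return updated lambda_bp (per-bp junction intensity).
#' @export
estimate_lambda <- function(segments, min_lambda = 1e-9) {
  if (nrow(segments) == 0) stop("no decoded segments")
  per <- split(segments, list(segments$line, segments$chrom), drop = TRUE)
  junctions <- sum(vapply(per, nrow, 0L) - 1L)
  total <- sum(segments$end - segments$start + 1)
  if (total <= 0) stop("zero decoded length")
  if (junctions == 0) {
    warning("no junctions decoded; lambda floored at ", min_lambda)
    return(min_lambda)
  }
  max(junctions / total, min_lambda)
}
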