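## small bin-matrix fixture with a planted multiallelic signal
make_bg <- function(G, chrom = "chr1", width = 1000) {
  B <- ncol(G)
  bm <- data.frame(chrom = chrom,
                   start = seq(1, by = width, length.out = B),
                   end = seq(width, by = width, length.out = B),
                   bin = seq_len(B))
  structure(list(map = bm, G = G,
                 line_ids = sprintf("L%03d", seq_len(nrow(G)))),
            class = "bin_genotypes")
}

test_that("gwas_lm matches textbook least squares on a hand example", {
  x <- c(0, 0, 1, 1, 2, 2, 0, 2)
  y <- c(1.0, 1.3, 2.1, 1.9, 3.2, 2.8, 0.9, 3.1)
  ## pad to the 30-line minimum with an independent block
  set.seed(401)
  x2 <- rbinom(22, 2, 0.5)
  y2 <- rnorm(22, 2, 1)
  g <- structure(list(G = matrix(c(x, x2), ncol = 1),
                      line_ids = sprintf("L%02d", 1:30),
                      marker_chrom = "chr1", marker_pos = 100),
                 class = "geno_matrix")
  res <- gwas_lm(g, c(y, y2), min_genotype_count = 1)
  fit <- lm(c(y, y2) ~ c(x, x2))
  expect_equal(res$effect, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$p, summary(fit)$coefficients[2, 4], tolerance = 1e-10)
  ## constant SNP is skipped
  g2 <- g; g2$G <- cbind(g$G, 1L)
  g2$marker_chrom <- rep("chr1", 2); g2$marker_pos <- c(100, 200)
  res2 <- gwas_lm(g2, c(y, y2), min_genotype_count = 1)
  expect_true(res2$skipped[2])
  expect_true(is.na(res2$p[2]))
})

test_that("null GWAS p-values are uniform with inflation near 1", {
  set.seed(402)
  n <- 120; m <- 400
  g <- structure(list(G = matrix(rbinom(n * m, 2, 0.4), n),
                      line_ids = sprintf("L%03d", 1:n),
                      marker_chrom = rep("chr1", m),
                      marker_pos = seq_len(m) * 1000),
                 class = "geno_matrix")
  y <- rnorm(n)
  res <- gwas_lm(g, y)
  ks <- suppressWarnings(ks.test(res$p[!res$skipped], "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(attr(res, "lambda_gc") - 1), 0.25)
})

test_that("BH step-up equals the brute-force rule", {
  ## worked example: sorted thresholds i*q/m = (0.0167, 0.0333, 0.05);
  ## the step-up stops at i = 2, so 0.02 is the cutoff
  bh <- bh_threshold(c(0.001, 0.02, 0.9), fdr = 0.05)
  expect_equal(bh$cutoff, 0.02)
  expect_equal(bh$discoveries, c(1L, 2L))
  expect_equal(bh_threshold(rep(1, 5))$discoveries, integer(0))
  ## permutation invariance
  p <- c(0.04, 0.01, 0.3, 0.01)
  expect_equal(bh_threshold(p)$cutoff, bh_threshold(rev(p))$cutoff)
  ## property: all vectors of length <= 10 against the definition
  set.seed(403)
  for (rep in 1:200) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    p[p == 0] <- 0.001
    got <- bh_threshold(p, 0.05)
    s <- sort(p)
    ok <- which(s <= seq_len(m) * 0.05 / m)
    cutoff <- if (length(ok)) s[max(ok)] else 0
    expect_equal(got$cutoff, cutoff)
    expect_equal(got$discoveries, which(p <= cutoff))
    ## agrees with p.adjust-based discovery set
    expect_setequal(got$discoveries, which(p.adjust(p, "BH") <= 0.05))
  }
})

test_that("locus clumping equals transitive-closure merging", {
  gw <- data.frame(chrom = "chr1", pos = c(1e6, 1.01e6, 2.5e6),
                   p = c(1e-8, 1e-7, 1e-9))
  loci <- clump_loci(gw, cutoff = 1e-6, window_bp = 6e5)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$lead_pos, c(1e6, 2.5e6))
  one <- clump_loci(gw, cutoff = 1e-6, window_bp = 2e6)
  expect_equal(nrow(one), 1)
  expect_equal(one$lead_pos, 2.5e6)   # smallest p leads
  ## randomized instances vs closure oracle
  set.seed(404)
  for (rep in 1:20) {
    pos <- sort(sample.int(5e6, 12))
    gwr <- data.frame(chrom = "chr1", pos = pos,
                      p = runif(12, 1e-10, 1e-7))
    lr <- clump_loci(gwr, cutoff = 1, window_bp = 3e5)
    grp <- oracle_clump(pos, 3e5)
    expect_equal(nrow(lr), length(unique(grp)))
    ## member spans agree
    spans <- t(vapply(unique(grp), function(g)
      range(pos[grp == g]), numeric(2)))
    expect_equal(lr$start, sort(spans[, 1]))
    expect_equal(lr$end, sort(spans[, 2]))
  }
})

test_that("LOD equals hand RSS arithmetic and is affine invariant", {
  ## n = 16, two founder groups with hand-set values
  lab <- rep(c(1L, 2L), each = 8)
  y <- c(10, 11, 9, 10.5, 10, 9.5, 11, 10,  14, 13, 15, 14.5, 13.5, 14, 15, 14)
  bg <- make_bg(matrix(lab, ncol = 1))
  sc <- linkage_scan(bg, y, min_group_n = 2)
  rss1 <- sum((y[1:8] - mean(y[1:8]))^2) + sum((y[9:16] - mean(y[9:16]))^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(sc$lod, (16 / 2) * log10(rss0 / rss1), tolerance = 1e-12)
  expect_equal(sc$n, 16L)
  expect_equal(sc$mean_1, mean(y[1:8]))
  ## affine transforms leave the LOD unchanged
  sc2 <- linkage_scan(bg, -2.5 * y + 7, min_group_n = 2)
  expect_equal(sc2$lod, sc$lod, tolerance = 1e-9)
  ## constant phenotype: LOD 0
  sc0 <- linkage_scan(bg, rep(3, 16), min_group_n = 2)
  expect_equal(sc0$lod, 0)
  ## single founder group after NA removal: LOD undefined
  bgNA <- make_bg(matrix(c(rep(1L, 8), rep(NA, 8)), ncol = 1))
  scNA <- linkage_scan(bgNA, y, min_group_n = 2)
  expect_true(is.na(scNA$lod))
})

test_that("stepwise cofactor selection finds planted bins, not noise", {
  set.seed(405)
  n <- 150; B <- 40
  G <- matrix(sample(1:8, n * B, replace = TRUE), n, B)
  ## smooth the matrix so neighbouring bins correlate (mosaic-like)
  for (b in 2:B) {
    keep <- runif(n) < 0.9
    G[keep, b] <- G[keep, b - 1]
  }
  bg <- make_bg(G, width = 5e5)
  ## pure-noise phenotype: empty or near-empty cofactor set
  y0 <- rnorm(n)
  cof0 <- icim_cofactors(bg, y0, min_group_n = 5)
  expect_lte(length(cof0), 1)
  ## planted major QTL at bin 20
  eff <- c(0, 0, 0, 0, 3, 3, 5, 6)
  y1 <- eff[G[, 20]] + rnorm(n, 0, 1.5)
  cof1 <- icim_cofactors(bg, y1, min_group_n = 5)
  expect_true(any(abs(cof1 - 20) <= 2))
  ## p_in = 1 admits the best bin even for noise
  cof_all <- icim_cofactors(bg, y0, p_in = 1, p_out = 2,
                            min_group_n = 5, max_cofactors = 1)
  expect_length(cof_all, 1)
})

test_that("permutation threshold is reproducible with quantile semantics", {
  set.seed(406)
  n <- 80
  G <- matrix(sample(1:8, n * 10, replace = TRUE), n, 10)
  bg <- make_bg(G, width = 1e5)
  y <- rnorm(n)
  p1 <- permutation_threshold(bg, y, n_perm = 100, seed = 9)
  p2 <- permutation_threshold(bg, y, n_perm = 100, seed = 9)
  expect_identical(p1, p2)
  expect_error(permutation_threshold(bg, y, n_perm = 50), "n_perm")
  ## alpha = 1: the minimum of the max-LOD distribution
  pmin_ <- permutation_threshold(bg, y, n_perm = 100, alpha = 1, seed = 9)
  expect_equal(pmin_$threshold, min(p1$max_lods))
  ## vectorised null max-LODs equal a direct per-permutation scan
  set.seed(9)
  P <- vapply(1:100, function(i) sample(y), numeric(n))
  direct <- vapply(1:5, function(i)
    max(linkage_scan(bg, P[, i], min_group_n = 1)$lod), 0)
  expect_equal(p1$max_lods[1:5], direct, tolerance = 1e-9)
})

test_that("QTL calling applies threshold, contiguity and 1.5-LOD drop", {
  lod <- c(0.2, 1, 4.2, 6, 4.8, 3.9, 0.5, 0.1, 4.5, 5.2, 0.3)
  sc <- data.frame(chrom = "chr1", start = seq(1, by = 1000,
                                               length.out = 11),
                   end = seq(1000, by = 1000, length.out = 11),
                   bin = 1:11, lod = lod)
  q <- call_qtls(sc, threshold = 4.0)
  expect_equal(nrow(q), 2)       # sub-threshold valley separates peaks
  expect_equal(q$lead_bin, c(4L, 10L))
  ## support interval: outward from the peak (LOD 6) until LOD < 4.5
  expect_equal(c(q$ci_start_bin[1], q$ci_end_bin[1]), c(4L, 5L))
  expect_equal(nrow(call_qtls(sc, threshold = 10)), 0)
})

test_that("PVE and founder effects equal hand arithmetic", {
  lab <- c(rep(1L, 4), rep(2L, 4), rep(3L, 4))
  y <- c(10, 11, 9, 10, 14, 15, 13, 14, 20, 19, 21, 20)
  bg <- make_bg(matrix(lab, ncol = 1))
  pe <- pve_and_effects(bg, y, 1, min_group_n = 3)
  fit <- lm(y ~ factor(lab))
  expect_equal(pe$pve, 100 * summary(fit)$r.squared, tolerance = 1e-12)
  gm <- tapply(y, lab, mean)
  expect_equal(pe$effects[1:3], as.numeric(gm - mean(y)))
  expect_equal(pe$additive_range, as.numeric(max(gm) - min(gm)) / 2)
  ## noiseless trait: PVE about 100
  y2 <- c(10, 10, 10, 10, 14, 14, 14, 14, 20, 20, 20, 20)
  expect_equal(pve_and_effects(bg, y2, 1, min_group_n = 3)$pve, 100)
})

test_that("offset distance follows the coordinate rules", {
  bm <- data.frame(chrom = "chr1",
                   start = c(1, 10001, 16001, 30001),
                   end = c(10000, 16000, 30000, 50000), bin = 1:4)
  qtl <- list(chrom = "chr1", lead_start = 16001, lead_end = 30000)
  ## gene inside the lead bin
  expect_equal(offset_distance(qtl, list(chrom = "chr1", start = 20000,
                                         end = 21000), bm),
               list(bp = 0, bins = 0L))
  ## gene 10 kb left with one whole bin strictly between
  od <- offset_distance(qtl, list(chrom = "chr1", start = 1,
                                  end = 6001), bm)
  expect_equal(od$bp, 10000)
  expect_equal(od$bins, 1L)
  ## abutting gene: 1 bp, 0 bins
  od2 <- offset_distance(qtl, list(chrom = "chr1", start = 15000,
                                   end = 16000), bm)
  expect_equal(od2$bp, 1)
  expect_equal(od2$bins, 0L)
  ## other chromosome: NA
  expect_true(is.na(offset_distance(qtl, list(chrom = "chr2", start = 1,
                                              end = 2), bm)$bp))
})

test_that("GWAS and linkage agree on a planted major QTL", {
  pop <- small_population(n_lines = 120, chrom_length = 6e6,
                          density = 2e-4, seed = 411)
  eff <- matrix(c(0, 0, 0, 0, 4, 4, 6, 8), 1)
  tm <- trait_model("chr1", 3e6, eff, env_effects = 0, residual_sd = 2)
  ph <- simulate_phenotypes(pop$mosaics, tm, pop$panel, seed = 412)
  geno <- observe_genotypes(pop$mosaics, pop$panel, e_hom = 0.005,
                            e_het = 0.005, seed = 413)
  y <- line_means(ph, geno$line_ids)
  gw <- gwas_lm(geno, y)
  lead_snp <- geno$marker_pos[which.min(gw$p)]
  seg <- infer_ancestry(geno, pop$panel, hmm_params())
  bm <- build_bins(seg, pop$panel$chrom_lengths)
  bg <- suppressWarnings(bin_genotypes(bm, seg))
  sc <- linkage_scan(bg, y[match(bg$line_ids, geno$line_ids)],
                     min_group_n = 10)
  q <- call_qtls(sc, threshold = 4)
  expect_gte(nrow(q), 1)
  top <- q[which.max(q$peak_lod), ]
  ## linkage support interval contains both the planted QTL and the
  ## GWAS lead SNP
  expect_true(top$ci_start <= 3e6 && top$ci_end >= 3e6)
  expect_true(top$ci_start <= lead_snp && top$ci_end >= lead_snp)
})
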