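test_that("founder simulation is deterministic and divergence drives FST", {
  p1 <- simulate_founders(n_chrom = 2, chrom_length = 2e6,
                          marker_density = 5e-4, seed = 11)
  p2 <- simulate_founders(n_chrom = 2, chrom_length = 2e6,
                          marker_density = 5e-4, seed = 11)
  expect_identical(p1, p2)
  ## every marker polymorphic
  for (mk in p1$markers) {
    cs <- colSums(mk$alleles)
    expect_true(all(cs > 0 & cs < 8))
  }
  ## no divergence -> two-group FST about 0
  p0 <- simulate_founders(n_chrom = 2, chrom_length = 4e6,
                          marker_density = 5e-4, divergence = 0, seed = 12)
  expect_lt(abs(founder_fst(p0)), 0.05)
  ## strong divergence -> FST matches an independent direct recomputation
  pd <- simulate_founders(n_chrom = 1, chrom_length = 4e6,
                          marker_density = 5e-4, divergence = 0.8,
                          seed = 13)
  expect_equal(founder_fst(pd), oracle_fst(pd), tolerance = 1e-12)
  expect_gt(founder_fst(pd), 0.4)
  ## parameter validation
  expect_error(simulate_founders(marker_density = 0), "density")
  expect_error(simulate_founders(chrom_length = -1), "positive")
})

test_that("meiosis respects map length and parental structure", {
  panel <- simulate_founders(n_chrom = 1, chrom_length = 1e6,
                             marker_density = 1e-5, seed = 3)
  plant <- magicmap:::new_mosaic(
    magicmap:::new_haplotype(1, panel$chrom_lengths),
    magicmap:::new_haplotype(2, panel$chrom_lengths))
  ## zero map length: gamete equals one whole parental haplotype, each
  ## about half the time
  set.seed(21)
  which_hap <- replicate(400, {
    g <- meiosis(plant, c(chr1 = 0))
    expect_equal(nrow(g$chr1), 1)
    g$chr1[1, 3]
  })
  expect_true(all(which_hap %in% 1:2))
  expect_gt(mean(which_hap == 1), 0.4)
  expect_lt(mean(which_hap == 1), 0.6)
  ## homozygous parent: gamete identical to the haplotype regardless of
  ## crossovers
  hom <- magicmap:::new_mosaic(
    magicmap:::new_haplotype(5, panel$chrom_lengths),
    magicmap:::new_haplotype(5, panel$chrom_lengths))
  g <- meiosis(hom, c(chr1 = 2))
  expect_equal(unname(g$chr1), unname(hom$haps[[1]]$chr1))
  ## 1-Morgan chromosome: crossover counts are Poisson(1)
  set.seed(22)
  counts <- replicate(10000, nrow(meiosis(plant, c(chr1 = 1))$chr1) - 1)
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 10000))
  obs <- tabulate(pmin(counts, 4) + 1, 5)
  expp <- c(dpois(0:3, 1), ppois(3, 1, lower.tail = FALSE)) * 10000
  chi <- sum((obs - expp)^2 / expp)
  expect_lt(chi, qchisq(0.999, 4))
})

test_that("gamete selection reproduces the enumeration arithmetic", {
  panel <- simulate_founders(n_chrom = 1, chrom_length = 1e6,
                             marker_density = 2e-5, seed = 5)
  locus <- selection_locus("pollen_killer", "chr1", 5e5,
                           carriers = panel$founder_ids[1:4], s = 1)
  het <- magicmap:::new_mosaic(
    magicmap:::new_haplotype(1, panel$chrom_lengths),
    magicmap:::new_haplotype(6, panel$chrom_lengths))
  morgans <- c(chr1 = 0.4)
  ## s = 1 selfing a heterozygote: offspring 1/2 killer-homozygote,
  ## 1/2 heterozygote; victim allele frequency 1/4
  set.seed(31)
  off <- replicate(1500, {
    o <- magicmap:::cross_plants(het, het, list(locus), panel, morgans)
    f1 <- o$haps[[1]]$chr1[findInterval(5e5, o$haps[[1]]$chr1[, 1]), 3]
    f2 <- o$haps[[2]]$chr1[findInterval(5e5, o$haps[[2]]$chr1[, 1]), 3]
    sum(c(f1, f2) %in% 5:8)   # victim allele count 0/1/2
  })
  expect_equal(sum(off == 2), 0)               # no victim homozygote
  vf <- mean(off) / 2
  expect_lt(abs(vf - 0.25), 3 * sqrt(0.25 * 0.75 / 2) / sqrt(1500))
  ## female killer-protector is the symmetric case
  locF <- selection_locus("female_killer_protector", "chr1", 5e5,
                          carriers = panel$founder_ids[1:4], s = 1)
  set.seed(32)
  offF <- replicate(1200, {
    o <- magicmap:::cross_plants(het, het, list(locF), panel, morgans)
    f1 <- o$haps[[1]]$chr1[findInterval(5e5, o$haps[[1]]$chr1[, 1]), 3]
    f2 <- o$haps[[2]]$chr1[findInterval(5e5, o$haps[[2]]$chr1[, 1]), 3]
    sum(c(f1, f2) %in% 5:8)
  })
  expect_equal(sum(offF == 2), 0)
  expect_lt(abs(mean(offF) / 2 - 0.25),
            3 * sqrt(0.25 * 0.75 / 2) / sqrt(1200))
  ## s = 0: exactly Mendelian filtering (nothing removed)
  locus0 <- selection_locus("pollen_killer", "chr1", 5e5,
                            carriers = panel$founder_ids[1:4], s = 0)
  set.seed(33)
  gs <- replicate(50, meiosis(het, morgans), simplify = FALSE)
  expect_length(apply_gamete_selection(gs, het, list(locus0), panel,
                                       "male"), 50)
  ## homozygous plants transmit Mendelianly even at s = 1
  homv <- magicmap:::new_mosaic(
    magicmap:::new_haplotype(6, panel$chrom_lengths),
    magicmap:::new_haplotype(6, panel$chrom_lengths))
  gs <- replicate(50, meiosis(homv, morgans), simplify = FALSE)
  expect_length(apply_gamete_selection(gs, homv, list(locus), panel,
                                       "male"), 50)
  expect_error(selection_locus("pollen_killer", "chr1", 1, "ZS97", s = 2),
               "s must be")
})

test_that("pedigree structure: tiling, funnel validation, F1 pattern", {
  pop <- small_population(n_lines = 12, chrom_length = 2e6, seed = 51)
  for (m in pop$mosaics) {
    expect_true(magicmap:::check_tiling(m$haps[[1]],
                                        pop$panel$chrom_lengths))
    expect_true(magicmap:::check_tiling(m$haps[[2]],
                                        pop$panel$chrom_lengths))
  }
  expect_error(crossing_design(10, funnel = c(1, 1, 2:7)), "funnel")
  expect_error(crossing_design(10, n_selfing_gens = -1), ">= 0")
  ## eight-way F1 (no selfing): heterozygous nearly everywhere, with
  ## founders from opposite four-way sides
  panel <- simulate_founders(n_chrom = 1, chrom_length = 5e6,
                             marker_density = 1e-5, seed = 52)
  f1s <- run_pedigree(panel, crossing_design(10, n_selfing_gens = 0),
                      seed = 53)
  for (m in f1s) {
    expect_gt(het_fraction(m), 0.99)
    expect_true(all(m$haps[[1]]$chr1[, 3] %in% 1:4))
    expect_true(all(m$haps[[2]]$chr1[, 3] %in% 5:8))
  }
})

test_that("neutral transmission and selfing inbreeding follow expectation", {
  pop <- small_population(n_lines = 150, chrom_length = 20e6, density = 1e-5,
                          seed = 61)
  shares <- vapply(pop$mosaics, founder_shares, numeric(8))
  for (k in 1:8) {
    se <- sd(shares[k, ]) / sqrt(ncol(shares))
    expect_lt(abs(mean(shares[k, ]) - 1 / 8), 3 * se)
  }
  ## heterozygosity halves per selfing generation
  for (g in c(1, 3, 6)) {
    pg <- small_population(n_lines = 60, chrom_length = 20e6,
                           density = 1e-5, n_selfing = g, seed = 70 + g)
    hf <- vapply(pg$mosaics, het_fraction, 0)
    se <- max(sd(hf) / sqrt(length(hf)), 1e-4)
    expect_lt(abs(mean(hf) - 0.5^g), 3 * se)
  }
})

test_that("junction counts increase with map length and selfing", {
  panel <- simulate_founders(n_chrom = 1, chrom_length = 20e6,
                             marker_density = 1e-5, seed = 81)
  mean_j <- function(cm_per_mb, gens, seed) {
    d <- crossing_design(25, n_selfing_gens = gens, cm_per_mb = cm_per_mb)
    mean(vapply(run_pedigree(panel, d, seed = seed), junction_count, 0))
  }
  by_map <- vapply(c(1, 4, 10), function(r) mean_j(r, 4, 82), 0)
  expect_true(all(diff(by_map) > 0))
  by_gen <- vapply(c(0, 3, 8), function(g) mean_j(4, g, 83), 0)
  expect_true(all(diff(by_gen) > 0))
})

test_that("full-funnel killer-locus frequency matches the Markov recursion", {
  panel <- simulate_founders(n_chrom = 1, chrom_length = 10e6,
                             marker_density = 2e-5, seed = 91)
  locus <- selection_locus("pollen_killer", "chr1", 5e6,
                           carriers = panel$founder_ids[1:4], s = 1)
  mos <- run_pedigree(panel, crossing_design(120, n_selfing_gens = 3),
                      list(locus), seed = 92)
  vf <- mean(vapply(mos, function(m) {
    f1 <- magicmap:::founder_at(m$haps[[1]]$chr1, 5e6)
    f2 <- magicmap:::founder_at(m$haps[[2]]$chr1, 5e6)
    sum(c(f1, f2) %in% 5:8) / 2
  }, 0))
  expected <- oracle_killer_freq(3, 1)
  se <- sqrt(expected * (1 - expected) / 120)
  expect_lt(abs(vf - expected), 3 * se + 1e-9)
})

test_that("zygote viability selection depletes the targeted combination", {
  panel <- simulate_founders(n_chrom = 2, chrom_length = 5e6,
                             marker_density = 2e-5, seed = 95)
  ## functional combination: founders 1-4 at both loci
  v <- viability_locus(chrom = c("chr1", "chr2"), pos = c(2e6, 3e6),
                       functional = list(panel$founder_ids[1:4],
                                         panel$founder_ids[1:4]),
                       s = 1)
  mos <- run_pedigree(panel, crossing_design(60, n_selfing_gens = 4),
                      list(v), seed = 96)
  affected <- vapply(mos, function(m)
    magicmap:::.viability_affected(m, v, panel), TRUE)
  neutral <- run_pedigree(panel, crossing_design(60, n_selfing_gens = 4),
                          seed = 97)
  affected0 <- vapply(neutral, function(m)
    magicmap:::.viability_affected(m, v, panel), TRUE)
  expect_equal(sum(affected), 0)
  expect_gt(sum(affected0), 0)
})

test_that("genotype observation applies the stated error model", {
  pop <- small_population(n_lines = 15, chrom_length = 2e6, seed = 101)
  clean <- observe_genotypes(pop$mosaics, pop$panel, e_hom = 0, e_het = 0)
  truth <- true_genotypes(pop$mosaics, pop$panel)
  expect_identical(clean$G, truth$G)
  ## forced error: true hom-ref never observed as 0
  forced <- observe_genotypes(pop$mosaics, pop$panel, e_hom = 1,
                              e_het = 0, seed = 102)
  hom_ref <- !is.na(truth$G) & truth$G == 0L
  expect_true(all(forced$G[hom_ref] != 0L))
  ## binomial rate check on wrong-homozygote calls
  e <- 0.005
  noisy <- observe_genotypes(pop$mosaics, pop$panel, e_hom = e,
                             e_het = 0, seed = 103)
  hom <- !is.na(truth$G) & truth$G != 1L
  n_hom <- sum(hom)
  flips <- sum(noisy$G[hom] == 2L - truth$G[hom])
  expect_lt(abs(flips / n_hom - e), 3 * sqrt(e * (1 - e) / n_hom))
  ## missingness
  miss <- observe_genotypes(pop$mosaics, pop$panel, missing_rate = 0.1,
                            seed = 104)
  expect_lt(abs(mean(is.na(miss$G)) - 0.1), 0.01)
  expect_error(observe_genotypes(pop$mosaics, pop$panel, e_hom = 0.7,
                                 e_het = 0.5), "e_hom")
})

test_that("trait model: noiseless classes, env offsets, QTL validation", {
  pop <- small_population(n_lines = 30, chrom_length = 2e6, seed = 111)
  effects <- matrix(c(0, 0, 0, 0, 9, 9, 14, 17), 1)
  tm <- trait_model("chr1", 1e6, effects, env_effects = c(0, 3),
                    residual_sd = 0, baseline = 80)
  ph <- simulate_phenotypes(pop$mosaics, tm, pop$panel, seed = 112)
  e1 <- ph$value[ph$env == "E1"]
  ## noiseless: every phenotype is baseline + an allele-effect value
  ## (homozygote levels or heterozygote midpoints)
  lv <- sort(unique(c(outer(effects[1, ], effects[1, ], "+") / 2)))
  expect_true(all(vapply(e1, function(v)
    any(abs(v - (80 + lv)) < 1e-9), TRUE)))
  ## environment offsets shift means by the stated amount
  expect_equal(mean(ph$value[ph$env == "E2"]) - mean(e1), 3)
  ## noisy env contrast within Monte-Carlo tolerance
  tm2 <- trait_model("chr1", 1e6, effects, env_effects = c(0, 3),
                     residual_sd = 2, baseline = 80)
  ph2 <- simulate_phenotypes(pop$mosaics, tm2, pop$panel, seed = 113)
  d <- mean(ph2$value[ph2$env == "E2"]) - mean(ph2$value[ph2$env == "E1"])
  expect_lt(abs(d - 3), 3 * 2 * sqrt(2 / 30))
  expect_error(trait_model("chr1", 1e6, effects, residual_sd = -1), "residual")
  bad <- trait_model("chr9", 1e6, effects)
  expect_error(simulate_phenotypes(pop$mosaics, bad, pop$panel),
               "off the simulated genome")
})
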