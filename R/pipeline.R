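## Run configuration and the end-to-end pipeline driver:
## simulate -> infer -> binmap -> scans -> reports.

#' Default run configuration
#'
#' All simulator, HMM and scan parameters with their defaults.  A config
#' file round-trips losslessly through YAML; unknown keys are rejected.
#'
#' @return nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1,
    sim = list(
      n_chrom = 3, chrom_length = 30e6, marker_density = 5e-4,
      divergence = 0.55, n_lines = 300, n_selfing_gens = 6,
      cm_per_mb = 4,
      e_hom = 0.005, e_het = 0.005, missing_rate = 0,
      qtl_chrom = c("chr1", "chr2", "chr3"),
      qtl_pos = c(15e6, 10e6, 20e6),
      qtl_effects = rbind(c(0, 0, 0, 0, 4.5, 4.5, 7, 8.5),
                          c(0, 1, 1, 2, 0, 2, 1, 2),
                          c(2, 0, 1, 0, 2, 1, 0, 1)),
      env_effects = c(0, 3), residual_sd = 3, baseline = 80),
    hmm = list(e_hom = 0.005, e_het = 0.026, lambda_bp = 3e-7,
               min_seg_bp = 5000),
    binmap = list(min_bin_bp = 5000, expansion_factor = 1),
    gwas = list(fdr = 0.05, clump_window_bp = 6e5,
                min_genotype_count = 5),
    linkage = list(p_in = 0.001, p_out = 0.002, min_group_n = 10,
                   exclusion_window_bp = 1e7, n_perm = 200,
                   alpha = 0.05),
    distortion = list(alpha = 0.05),
    recomb = list(window_bp = 1e6, q_cut = 0.05)
  )
}

#' Read a YAML run configuration
#'
#' Values are merged over \code{\link{default_config}}; unknown keys are
#' an error.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_config()
  merge_into <- function(def, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(def))
        stop("unknown config key: ", prefix, k)
      if (is.list(def[[k]])) {
        def[[k]] <- merge_into(def[[k]], user[[k]], paste0(prefix, k, "."))
      } else {
        v <- user[[k]]
        if (k == "qtl_effects") v <- do.call(rbind, v)
        def[[k]] <- v
      }
    }
    def
  }
  merge_into(def, user)
}

#' Write a run configuration as YAML
#' @param config configuration list.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  cfg$sim$qtl_effects <- lapply(seq_len(nrow(config$sim$qtl_effects)),
                                function(i) config$sim$qtl_effects[i, ])
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: simulate (founders, pedigree, genotypes, phenotypes) ->
#' ancestry inference -> bin map -> GWAS + linkage scans -> distortion +
#' recombination scans -> allele report; every output file carries a
#' provenance header (package version, seed, config hash) and identical
#' config + seed reproduce identical payloads.
#'
#' @param config configuration list (see \code{\link{default_config}}).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_run_config(config, cfg_path)
  hash <- as.character(tools::md5sum(cfg_path))
  prov <- .prov_header(config$seed, hash)
  set.seed(config$seed)
  s <- config$sim
  ## --- simulate ---
  panel <- simulate_founders(n_chrom = s$n_chrom,
                             chrom_length = s$chrom_length,
                             marker_density = s$marker_density,
                             divergence = s$divergence)
  design <- crossing_design(n_lines = s$n_lines,
                            n_selfing_gens = s$n_selfing_gens,
                            cm_per_mb = s$cm_per_mb)
  mosaics <- run_pedigree(panel, design)
  geno <- observe_genotypes(mosaics, panel, e_hom = s$e_hom,
                            e_het = s$e_het,
                            missing_rate = s$missing_rate)
  trait <- trait_model(chrom = s$qtl_chrom, pos = s$qtl_pos,
                       effects = s$qtl_effects,
                       env_effects = s$env_effects,
                       residual_sd = s$residual_sd,
                       baseline = s$baseline)
  pheno <- simulate_phenotypes(mosaics, trait, panel)
  write_genotypes_csv(panel, geno, file.path(outdir, "genotypes.csv"))
  write_phenotypes(pheno, file.path(outdir, "phenotypes.csv"))
  write_segments(mosaic_segments(mosaics),
                 file.path(outdir, "truth_segments.tsv"),
                 provenance = prov)
  ## --- infer ancestry ---
  params <- hmm_params(e_hom = config$hmm$e_hom, e_het = config$hmm$e_het,
                       lambda_bp = config$hmm$lambda_bp,
                       min_seg_bp = config$hmm$min_seg_bp)
  segments <- infer_ancestry(geno, panel, params)
  write_segments(segments, file.path(outdir, "segments.tsv"),
                 provenance = prov)
  ## --- bin map ---
  bm <- build_bins(segments, panel$chrom_lengths,
                   min_bin_bp = config$binmap$min_bin_bp)
  bg <- bin_genotypes(bm, segments)
  gmap <- genetic_map_from_bins(bg, config$binmap$expansion_factor)
  .write_tsv(as.data.frame(bm), file.path(outdir, "bin_map.tsv"), prov)
  .write_tsv(gmap, file.path(outdir, "genetic_map.tsv"), prov)
  ## --- trait scans ---
  y <- line_means(pheno, geno$line_ids)
  gwas <- gwas_lm(geno, y,
                  min_genotype_count = config$gwas$min_genotype_count)
  bh <- bh_threshold(gwas$p, config$gwas$fdr)
  loci <- clump_loci(gwas, bh$cutoff, config$gwas$clump_window_bp)
  cof <- icim_cofactors(bg, y, p_in = config$linkage$p_in,
                        p_out = config$linkage$p_out,
                        min_group_n = config$linkage$min_group_n)
  scan <- linkage_scan(bg, y, cof,
                       exclusion_window_bp =
                         config$linkage$exclusion_window_bp,
                       min_group_n = config$linkage$min_group_n)
  perm <- permutation_threshold(bg, y, n_perm = config$linkage$n_perm,
                                alpha = config$linkage$alpha,
                                seed = config$seed)
  qtls <- call_qtls(scan, perm$threshold)
  if (nrow(qtls)) {
    pe <- lapply(qtls$lead_bin, function(b)
      pve_and_effects(bg, y, b, config$linkage$min_group_n))
    qtls$pve <- vapply(pe, `[[`, 0, "pve")
    qtls$additive_range <- vapply(pe, `[[`, 0, "additive_range")
  }
  .write_tsv(gwas, file.path(outdir, "gwas.tsv"), prov)
  .write_tsv(loci, file.path(outdir, "gwas_loci.tsv"), prov)
  .write_tsv(as.data.frame(scan), file.path(outdir, "linkage.tsv"), prov)
  .write_tsv(qtls, file.path(outdir, "qtls.tsv"), prov)
  ## --- genome scans ---
  cnt <- bin_founder_freqs(bg)
  dt <- distortion_test(cnt)
  regions <- merge_distortion_regions(dt$p, bm, cnt,
                                      config$distortion$alpha)
  rw <- recomb_windows(bg, panel$chrom_lengths, gmap,
                       window_bp = config$recomb$window_bp,
                       q_cut = config$recomb$q_cut)
  .write_tsv(regions, file.path(outdir, "distortion_regions.tsv"), prov)
  .write_tsv(rw, file.path(outdir, "recomb_windows.tsv"), prov)
  ## --- allele report + summary ---
  allele_report <- NULL
  if (nrow(qtls)) {
    allele_report <- do.call(rbind, lapply(seq_len(nrow(qtls)), function(i) {
      gr <- try(founder_group_means(bg$G[, qtls$lead_bin[i]], y,
                                    config$linkage$min_group_n,
                                    panel$founder_ids), silent = TRUE)
      if (inherits(gr, "try-error")) return(NULL)
      d <- duncan_mrt(gr)
      lev <- classify_effect_levels(d)
      cbind(qtl = i, lead_bin = qtls$lead_bin[i], lev$assignment)
    }))
    if (!is.null(allele_report))
      .write_tsv(allele_report, file.path(outdir, "allele_report.tsv"),
                 prov)
  }
  h2 <- broad_sense_heritability(pheno)
  summary <- list(
    version = as.character(packageVersion("magicmap")),
    seed = config$seed, config_hash = hash,
    n_lines = length(mosaics), n_markers = ncol(geno$G),
    n_bins = nrow(bm), n_gwas_loci = nrow(loci),
    n_qtls = nrow(qtls), n_distortion_regions = nrow(regions),
    lod_threshold = perm$threshold, H2 = h2$H2,
    het_fraction = population_summaries(geno)$het_fraction)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(panel = panel, mosaics = mosaics, geno = geno,
                 pheno = pheno, segments = segments, bin_map = bm,
                 bin_geno = bg, genetic_map = gmap, gwas = gwas,
                 gwas_loci = loci, scan = scan, qtls = qtls,
                 perm = perm, distortion = regions, recomb = rw,
                 allele_report = allele_report, summary = summary))
}
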