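## Readers and writers for the standard formats.  Coordinates are 1-based
## inclusive in TSV/CSV; BED output is 0-based half-open.  Numeric output
## uses 6 significant digits.

.prov_header <- function(seed = NA, config_hash = NA) {
  c(sprintf("# magicmap %s", as.character(packageVersion("magicmap"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash))
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write founder + offspring genotypes as VCF
#'
#' Biallelic sites; founders and lines appear as samples with
#' unphased homozygous/heterozygous GT calls; missing calls are "./.".
#' Founder haploid 0/1 alleles are written as homozygous diploid GT.
#'
#' @param panel a \code{founder_panel}.
#' @param geno a \code{geno_matrix} of offspring (optional; founders-only
#'   VCF if NULL).
#' @param path output path.
#' @export
write_genotypes_vcf <- function(panel, geno = NULL, path) {
  samples <- panel$founder_ids
  if (!is.null(geno)) samples <- c(samples, geno$line_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=magicmap_%s", as.character(packageVersion("magicmap"))),
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom_names,
            as.integer(panel$chrom_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  col <- 0
  for (c in panel$chrom_names) {
    pos <- panel$markers[[c]]$pos
    al <- panel$markers[[c]]$alleles
    for (j in seq_along(pos)) {
      col <- col + 1
      f_gt <- gt_code[2 * al[, j] + 1]
      row <- c(c, pos[j], sprintf("%s_%d", c, pos[j]), "A", "T", ".",
               "PASS", ".", "GT", f_gt)
      if (!is.null(geno)) {
        g <- geno$G[, col]
        o_gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
        row <- c(row, o_gt)
      }
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read founder + offspring genotypes from VCF or wide CSV
#'
#' Samples are partitioned into founders and offspring by
#' \code{founder_ids}; a missing founder sample is fatal.  Multiallelic
#' records are skipped (count reported via message).  Phased ("|") and
#' unphased ("/") GT separators are accepted equivalently.
#'
#' @param path a .vcf (via vcfR) or .csv file (columns chrom, pos, then
#'   one column per sample with 0/1/2/NA dosages).
#' @param founder_ids founder sample names (order defines founder
#'   indices).
#' @param chrom_lengths named bp lengths (markers beyond a length are an
#'   error); inferred as max position per chromosome when NULL.
#' @return list with \code{panel} (a \code{founder_panel}) and
#'   \code{geno} (a \code{geno_matrix} of the remaining samples).
#' @export
read_genotypes <- function(path, founder_ids, chrom_lengths = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
      message(sum(multi), " multiallelic records skipped")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean %in% c("0/0")] <- 0L
    dos[clean %in% c("0/1", "1/0")] <- 1L
    dos[clean %in% c("1/1")] <- 2L
    df <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]))
    df <- cbind(df, as.data.frame(dos))
  } else {
    df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                     stringsAsFactors = FALSE, check.names = FALSE)
  }
  samples <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
  missing_f <- setdiff(founder_ids, samples)
  if (length(missing_f))
    stop("founder sample(s) missing: ", paste(missing_f, collapse = ", "))
  offspring <- setdiff(samples, founder_ids)
  ord <- order(match(df$chrom, unique(df$chrom)), df$pos)
  df <- df[ord, ]
  chroms <- unique(df$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(c)
      max(df$pos[df$chrom == c]), 0)
  markers <- lapply(chroms, function(c) {
    sel <- df$chrom == c
    fa <- t(as.matrix(df[sel, founder_ids, drop = FALSE])) / 2
    ## founder samples are inbred: dosage 0/2 -> allele 0/1
    list(pos = df$pos[sel],
         alleles = matrix(as.integer(round(fa)), nrow = length(founder_ids)))
  })
  names(markers) <- chroms
  panel <- structure(list(
    founder_ids = founder_ids,
    group = setNames(rep(NA_character_, length(founder_ids)), founder_ids),
    chrom_names = chroms,
    chrom_lengths = chrom_lengths[chroms],
    markers = markers), class = "founder_panel")
  geno <- NULL
  if (length(offspring)) {
    geno <- structure(list(
      G = t(as.matrix(df[, offspring, drop = FALSE])),
      line_ids = offspring,
      marker_chrom = df$chrom, marker_pos = df$pos),
      class = "geno_matrix")
    storage.mode(geno$G) <- "integer"
  }
  list(panel = panel, geno = geno)
}

#' Write genotypes as wide CSV
#'
#' Columns chrom, pos, one column per founder then per line; dosages
#' 0/1/2, NA blank.  Founders are written as 0/2 (homozygous dosage).
#' @inheritParams write_genotypes_vcf
#' @export
write_genotypes_csv <- function(panel, geno = NULL, path) {
  chrom <- unlist(lapply(panel$chrom_names, function(c)
    rep(c, length(panel$markers[[c]]$pos))))
  pos <- unlist(lapply(panel$chrom_names, function(c)
    panel$markers[[c]]$pos))
  fa <- do.call(cbind, lapply(panel$chrom_names, function(c)
    panel$markers[[c]]$alleles)) * 2L
  df <- data.frame(chrom = chrom, pos = pos)
  fdf <- as.data.frame(t(fa))
  names(fdf) <- panel$founder_ids
  df <- cbind(df, fdf)
  if (!is.null(geno)) {
    odf <- as.data.frame(t(geno$G))
    names(odf) <- geno$line_ids
    df <- cbind(df, odf)
  }
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ancestry segments as BED-like TSV
#'
#' Columns chrom, start, end, line, founder, mean_posterior (1-based
#' inclusive coordinates; use \code{bed = TRUE} for 0-based half-open).
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @param bed convert to BED coordinates.
#' @param provenance optional character header lines.
#' @export
write_segments <- function(segments, path, bed = FALSE,
                           provenance = NULL) {
  df <- segments
  if (bed) {
    df$start <- df$start - 1
  }
  .write_tsv(df, path, provenance)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) .read_tsv(path)

#' Write / read a long-format phenotype table (line, env, value)
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
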