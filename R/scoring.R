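#' Default discovery p-value threshold grid
#'
#' Six increasingly inclusive discovery-GWAS p-value thresholds at which
#' polygenic scores are computed. Threshold sets are nested: every SNP
#' passing a stricter threshold also passes a looser one.
#'
#' @return sorted numeric vector of six thresholds.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.05)
}

#' Map SNPs to a gene set with a flanking window
#'
#' Returns the ids of SNPs lying within `window` bp of any gene in the set:
#' position in `[gene_start - window, gene_end + window]` (1-based,
#' inclusive at both bounds), unioned over genes so each SNP appears once.
#' Uses GenomicRanges interval overlap.
#'
#' @param snp_map data.frame with id, chrom, pos (1-based).
#' @param genes data.frame with name, chrom, start, end (1-based inclusive).
#' @param window flank in bp (default 20000, i.e. 20 kb).
#' @return character vector of SNP ids (possibly empty).
#' @export
map_snps_to_pathway <- function(snp_map, genes, window = 20000) {
  if (nrow(genes) == 0L) return(character(0))
  common <- intersect(unique(as.character(snp_map$chrom)),
                      unique(as.character(genes$chrom)))
  if (length(common) == 0L) {
    warning("no chromosome shared between SNP map and gene set",
            call. = FALSE)
    return(character(0))
  }
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(snp_map$chrom),
    ranges = IRanges::IRanges(start = snp_map$pos, width = 1L))
  win <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - window),
                              end = genes$end + window))
  hits <- GenomicRanges::findOverlaps(snps, win)
  snp_map$id[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Align summary-statistic effect alleles to dosage-counted alleles
#'
#' Matches SNPs between the target genotype map and the discovery summary
#' statistics by id, reconciles allele coding, and attaches the log
#' odds-ratio weight to the dosage-counted allele. When the counted allele
#' is the summary-statistic *other* allele, the record is flagged `flip`
#' and the dosage is reflected (`2 - dosage`) at scoring time. Allele pairs
#' matching only after strand complementing are accepted;
#' strand-ambiguous SNPs (A/T, C/G) are dropped by default, and
#' irreconcilable pairs are always dropped, both with counts reported.
#'
#' @param snp_map genotype SNP map (id, allele1 = counted, allele2).
#' @param sumstats `summary_stats` table.
#' @param drop_ambiguous drop A/T and C/G SNPs (default TRUE).
#' @return data.frame of class `aligned_weights`: id, weight = log(OR) for
#'   the counted allele's orientation, flip, p_value; attributes
#'   `n_ambiguous` and `n_irreconcilable` count the exclusions.
#' @export
align_alleles <- function(snp_map, sumstats, drop_ambiguous = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  j <- match(snp_map$id, sumstats$id)
  keep <- !is.na(j)
  map <- snp_map[keep, , drop = FALSE]
  ss <- sumstats[j[keep], , drop = FALSE]

  a1 <- toupper(map$allele1); a2 <- toupper(map$allele2)
  ea <- toupper(ss$effect_allele); oa <- toupper(ss$other_allele)
  ambiguous <- a1 == comp[a2]
  direct <- a1 == ea & a2 == oa
  flipped <- a1 == oa & a2 == ea
  # strand-complemented matches (meaningful only for unambiguous pairs)
  direct_c <- comp[a1] == ea & comp[a2] == oa
  flipped_c <- comp[a1] == oa & comp[a2] == ea
  match_dir <- direct | (!ambiguous & direct_c)
  match_flip <- flipped | (!ambiguous & flipped_c)
  irreconcilable <- !(match_dir | match_flip)

  drop <- irreconcilable | (drop_ambiguous & ambiguous)
  n_amb <- sum(ambiguous & !irreconcilable & drop_ambiguous)
  n_irr <- sum(irreconcilable)
  if (n_amb + n_irr > 0)
    message(sprintf("align_alleles: dropped %d strand-ambiguous and %d irreconcilable SNP(s)",
                    n_amb, n_irr))
  out <- data.frame(
    id = map$id[!drop],
    weight = log(ss$odds_ratio[!drop]),
    flip = match_flip[!drop],
    p_value = ss$p_value[!drop],
    stringsAsFactors = FALSE
  )
  attr(out, "n_ambiguous") <- n_amb
  attr(out, "n_irreconcilable") <- n_irr
  class(out) <- c("aligned_weights", "data.frame")
  out
}

#' Select SNPs passing a discovery p-value threshold
#'
#' @param sumstats any table with `id` and a p-value column (`p_value`).
#' @param threshold p-value threshold in (0, 1]; SNPs with `p <= threshold`
#'   are returned.
#' @return character vector of SNP ids.
#' @export
select_by_threshold <- function(sumstats, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  p <- if ("p_value" %in% names(sumstats)) sumstats$p_value else sumstats$p
  sumstats$id[!is.na(p) & p <= threshold]
}

#' Compute a polygenic score over a SNP set
#'
#' `score_i = sum_s w_s * d_is` over the SNPs in the set, where `w_s` is the
#' aligned log odds-ratio weight and `d_is` the dosage of the effect allele
#' (reflected, `2 - dosage`, for flipped records). Missing dosages are
#' imputed as twice the target-sample allele frequency, which leaves the
#' score expectation unchanged.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights an `aligned_weights` table.
#' @param snp_set character vector of SNP ids to include (intersected with
#'   the aligned weights and the genotype columns).
#' @param average divide by the number of SNPs used (default FALSE: scores
#'   are sums).
#' @return list with `score` (named numeric per individual) and `n_snps`.
#' @export
compute_prs <- function(genotypes, weights, snp_set, average = FALSE) {
  use <- weights[weights$id %in% snp_set &
                   weights$id %in% colnames(genotypes$dosages), ,
                 drop = FALSE]
  n <- nrow(genotypes$dosages)
  if (nrow(use) == 0L)
    return(list(score = setNames(rep(NA_real_, n), genotypes$sample_ids),
                n_snps = 0L))
  d <- genotypes$dosages[, use$id, drop = FALSE]
  if (anyNA(d)) {
    freq <- colMeans(d, na.rm = TRUE)        # 2 * target-sample MAF
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- freq[idx[, 2]]
  }
  if (any(use$flip)) d[, use$flip] <- 2 - d[, use$flip, drop = FALSE]
  score <- as.vector(d %*% use$weight)
  if (average) score <- score / nrow(use)
  list(score = setNames(score, genotypes$sample_ids), n_snps = nrow(use))
}

#' Pathway polygenic score profiles over a threshold grid
#'
#' For every pathway in the collection and every threshold in the grid,
#' restricts the aligned summary statistics to SNPs within `window` bp of
#' the pathway's genes that pass the threshold, and computes the
#' log-OR-weighted dosage score for every individual.
#'
#' @param genotypes a `genotype_matrix`.
#' @param sumstats a `summary_stats` table.
#' @param annotation a `pathway_collection`.
#' @param window gene flank in bp (default 20000).
#' @param thresholds p-value grid (default [default_thresholds()]).
#' @param pathways which sets to score (default all in the collection).
#' @param average per-SNP averaging instead of summing (default FALSE).
#' @param drop_ambiguous passed to [align_alleles()].
#'
#' The set named `"genome_wide"` is not restricted to gene windows: the
#' overall polygenic score uses every aligned SNP passing the threshold.
#' @return long data.frame of class `prs_profile`: sample_id, pathway,
#'   threshold, score, n_snps. Cells with no surviving SNP have NA score
#'   and n_snps 0.
#' @export
score_pathways <- function(genotypes, sumstats, annotation,
                           window = 20000,
                           thresholds = default_thresholds(),
                           pathways = names(annotation$pathways),
                           average = FALSE,
                           drop_ambiguous = TRUE) {
  thresholds <- sort(thresholds)
  aligned <- align_alleles(genotypes$snp_map, sumstats, drop_ambiguous)
  genes <- annotation$genes
  out <- list()
  for (pw in pathways) {
    if (pw == "genome_wide") {
      in_win <- genotypes$snp_map$id
    } else {
      gset <- genes[genes$name %in% annotation$pathways[[pw]], ,
                    drop = FALSE]
      in_win <- map_snps_to_pathway(genotypes$snp_map, gset, window)
    }
    for (th in thresholds) {
      pass <- select_by_threshold(aligned, th)
      prs <- compute_prs(genotypes, aligned, intersect(in_win, pass),
                         average = average)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = genotypes$sample_ids, pathway = pw, threshold = th,
        score = unname(prs$score), n_snps = prs$n_snps,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("prs_profile", "data.frame")
  res
}
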