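#' @section File conventions:
#' Tabular outputs are TSV with '#'-prefixed metadata header lines (package
#' version, seed, config hash) so files are diff-friendly and
#' self-describing; readers skip '#' lines.
#' @name endopgs-io
NULL

meta_header <- function(seed = NA) {
  c(sprintf("# endopgs %s",
            as.character(utils::packageVersion("endopgs"))),
    sprintf("# seed=%s", seed))
}

write_tsv_meta <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  head <- readLines(path, n = 100L)
  n_meta <- match(FALSE, startsWith(head, "#")) - 1L
  if (is.na(n_meta)) stop("no data lines in ", path, call. = FALSE)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = n_meta, data.table = FALSE,
                                  check.names = FALSE))
}

#' Write / read a dosage matrix as TSV
#'
#' Layout: SNP map columns (id, chrom, pos, allele1, allele2, maf) followed
#' by one column per individual holding that individual's dosage of
#' allele1.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file.
#' @param seed seed recorded in the metadata header.
#' @return `write_dosage_tsv`: the path, invisibly. `read_dosage_tsv`: a
#'   `genotype_matrix`.
#' @export
write_dosage_tsv <- function(genotypes, path, seed = NA) {
  df <- cbind(genotypes$snp_map,
              as.data.frame(t(genotypes$dosages), check.names = FALSE))
  write_tsv_meta(df, path, seed)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv_meta(path)
  map_cols <- c("id", "chrom", "pos", "allele1", "allele2", "maf")
  stopifnot(all(map_cols %in% names(df)))
  snp_map <- df[, map_cols]
  dos <- t(as.matrix(df[, setdiff(names(df), map_cols), drop = FALSE]))
  colnames(dos) <- snp_map$id
  structure(list(dosages = dos, snp_map = snp_map,
                 sample_ids = rownames(dos)),
            class = "genotype_matrix")
}

#' Write / read genotypes as VCF with a DS (dosage) FORMAT field
#'
#' The writer emits a minimal VCF 4.2 file: allele2 as REF, allele1 (the
#' counted allele) as ALT, and per-sample DS = dosage of ALT. The reader
#' parses VCF through VariantAnnotation, preferring DS and falling back to
#' GT allele counts; multi-allelic records are skipped with a warning.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path (uncompressed `.vcf`).
#' @return `write_vcf`: path invisibly; `read_vcf`: a `genotype_matrix`
#'   (maf recomputed from the dosages).
#' @export
write_vcf <- function(genotypes, path) {
  map <- genotypes$snp_map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=endopgs-%s",
            as.character(utils::packageVersion("endopgs"))),
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Dosage of the ALT allele\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  ), con)
  ds <- format(t(genotypes$dosages), trim = TRUE, digits = 6,
               scientific = FALSE)
  body <- paste(map$chrom, map$pos, map$id, map$allele2, map$allele1,
                ".", "PASS", ".", "DS",
                apply(ds, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) != 1L
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    dos <- t(gen$DS)
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT
    cnt <- matrix(vapply(strsplit(gt, "[/|]"), function(a)
      sum(a == "1"), numeric(1)), nrow(gt), ncol(gt))
    dimnames(cnt) <- dimnames(gt)
    dos <- t(cnt)
  } else stop("VCF has neither DS nor GT", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  snp_map <- data.frame(
    id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    allele1 = as.character(unlist(alt)),
    allele2 = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE)
  snp_map$maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  colnames(dos) <- snp_map$id
  structure(list(dosages = dos, snp_map = snp_map,
                 sample_ids = rownames(dos)),
            class = "genotype_matrix")
}

#' Write / read discovery summary statistics TSV
#'
#' Columns SNP, CHR, BP, A1 (effect allele), A2, OR, P. Simulation-truth
#' columns present in memory are not written.
#'
#' @param sumstats a `summary_stats` table.
#' @param path file path.
#' @param seed seed for the metadata header.
#' @return writer: path invisibly; reader: `summary_stats` data.frame.
#' @export
write_sumstats <- function(sumstats, path, seed = NA) {
  df <- data.frame(SNP = sumstats$id, CHR = sumstats$chrom,
                   BP = sumstats$pos, A1 = sumstats$effect_allele,
                   A2 = sumstats$other_allele,
                   OR = sumstats$odds_ratio, P = sumstats$p_value)
  write_tsv_meta(df, path, seed)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read_tsv_meta(path)
  stopifnot(all(c("SNP", "CHR", "BP", "A1", "A2", "OR", "P") %in% names(df)))
  if (any(df$OR <= 0)) stop("odds ratios must be positive", call. = FALSE)
  if (anyDuplicated(df$SNP)) stop("duplicate SNP ids", call. = FALSE)
  out <- data.frame(id = df$SNP, chrom = df$CHR, pos = df$BP,
                    effect_allele = df$A1, other_allele = df$A2,
                    odds_ratio = df$OR, p_value = df$P,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read gene coordinates as BED
#'
#' BED is 0-based half-open; internal gene records are 1-based inclusive.
#' Reading and writing go through rtracklayer, which performs the
#' conversion.
#'
#' @param genes data.frame: name, chrom, start, end (1-based inclusive).
#' @param path `.bed` path.
#' @return writer: path invisibly; reader: genes data.frame (1-based).
#' @export
write_genes_bed <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end,
                              names = genes$name))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_genes_bed
#' @export
read_genes_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED", call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(name = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write / read pathway gene sets as GMT
#'
#' GMT: one set per line — name, description, then member gene names, all
#' tab-separated. No installed package provides a GMT parser, so this is a
#' minimal hand-rolled reader/writer for that one-line-per-set format.
#'
#' @param pathways named list of gene-name character vectors.
#' @param path `.gmt` path.
#' @return writer: path invisibly; reader: named list.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40),
                             call. = FALSE)
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Resolve GMT gene sets against gene coordinates
#'
#' Joins GMT set membership to BED-derived gene records, producing the
#' `pathway_collection` the scoring module consumes. Unresolved gene names
#' are counted and reported; sets flagged autosome-only can drop
#' non-autosomal genes (simulated chromosomes are all autosomes, so the
#' flag is a pass-through there).
#'
#' @param pathways named list from [read_gmt()].
#' @param genes data.frame from [read_genes_bed()].
#' @return a `pathway_collection`; attribute `n_unresolved` counts dropped
#'   names per set.
#' @export
resolve_gene_sets <- function(pathways, genes) {
  unresolved <- integer(length(pathways))
  names(unresolved) <- names(pathways)
  resolved <- lapply(names(pathways), function(nm) {
    found <- pathways[[nm]] %in% genes$name
    unresolved[nm] <<- sum(!found)
    pathways[[nm]][found]
  })
  names(resolved) <- names(pathways)
  if (sum(unresolved) > 0)
    message("resolve_gene_sets: ", sum(unresolved),
            " unresolved gene name(s)")
  if (all(lengths(resolved) == 0L))
    stop("no gene set resolved against the gene coordinates", call. = FALSE)
  structure(list(genes = genes, pathways = resolved),
            class = "pathway_collection",
            n_unresolved = unresolved)
}

#' Write / read the phenotype table
#'
#' @param table a `phenotype_table`.
#' @param path TSV path.
#' @param seed seed for the metadata header.
#' @return writer: path invisibly; reader: `phenotype_table`.
#' @export
write_phenotypes <- function(table, path, seed = NA) {
  write_tsv_meta(as.data.frame(table), path, seed)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_meta(path)
  class(df) <- c("phenotype_table", "data.frame")
  df
}
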