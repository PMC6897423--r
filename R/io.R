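# Readers/writers for the standard interchange formats.

#' Write a simulated cohort to disk (VCF, FASTA, GFF3, TSV, JSON)
#'
#' Emits a multi-sample VCF 4.2 (diploid GT with DP and GQ), the reference
#' FASTA, a GFF3 gene annotation (gene + CDS features, 1-based closed
#' intervals), the truth set and config as JSON.
#'
#' @param cohort A `neoy_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             fasta = file.path(dir, "reference.fa"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.json"))
  write_genotype_vcf(cohort$genotypes, cohort$indel_genotypes, paths["vcf"],
                     chrom = cohort$chrom, contig_length = cohort$config$chromosome_length)
  seq <- Biostrings::DNAStringSet(chars_to_string(cohort$reference))
  names(seq) <- cohort$chrom
  Biostrings::writeXStringSet(seq, paths["fasta"])
  write_genes_gff3(cohort$genes, paths["gff"], chrom = cohort$chrom)
  truth <- cohort$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  cfgout <- cohort$config; class(cfgout) <- NULL
  jsonlite::write_json(cfgout, paths["config"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

# long genotype table (+ optional indel table) -> multi-sample VCF text
write_genotype_vcf <- function(genotypes, indel_genotypes = NULL, path,
                               chrom = "neoChr", contig_length = NA) {
  g <- data.table::as.data.table(genotypes)
  samples <- sort(unique(g$sample))
  fmt_site <- function(dt, p) {
    ref <- dt$ref[1]
    alleles <- sort(setdiff(unique(stats::na.omit(c(dt$a1, dt$a2))), ref))
    code <- stats::setNames(seq_along(alleles), alleles)
    gt_of <- function(a) ifelse(is.na(a), ".", ifelse(a == ref, "0", code[a]))
    dt <- dt[match(samples, sample)]
    cells <- paste0(gt_of(dt$a1), "/", gt_of(dt$a2), ":",
                    ifelse(is.na(dt$dp), ".", dt$dp), ":",
                    ifelse(is.na(dt$gq), ".", dt$gq))
    paste(c(chrom, p, ".", ref,
            if (length(alleles)) paste(alleles, collapse = ",") else ".",
            ".", "PASS", ".", "GT:DP:GQ", cells), collapse = "\t")
  }
  body <- g[order(pos), fmt_site(.SD, .BY$pos), by = pos]$V1
  if (!is.null(indel_genotypes) && nrow(indel_genotypes %||% data.frame())) {
    id <- data.table::as.data.table(indel_genotypes)
    isamp <- sort(unique(id$sample))
    ibody <- id[order(pos), {
      ref1 <- ref[1]; alt1 <- alt[1]
      cells <- vapply(samples, function(s) {
        i <- match(s, sample)
        if (is.na(i) || !(s %in% isamp)) return("./.:.:.")
        g1 <- if (a1[i] == ref1) "0" else "1"
        g2 <- if (a2[i] == ref1) "0" else "1"
        paste0(g1, "/", g2, ":", dp[i], ":", gq[i])
      }, character(1))
      .(line = paste(c("neoChr", pos[1], ".", ref1, alt1, ".", "PASS", ".",
                       "GT:DP:GQ", cells), collapse = "\t"))
    }, by = pos]$line
    body <- c(body, ibody)
    ord <- order(as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2)))
    body <- body[ord]
  }
  header <- c("##fileformat=VCFv4.2",
              if (!is.na(contig_length))
                sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(contig_length)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

write_genes_gff3 <- function(genes, path, chrom = "neoChr") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = rep(genes$start, 2), end = rep(genes$end, 2)),
    strand = rep(genes$strand, 2),
    type = rep(c("gene", "CDS"), each = nrow(genes)),
    ID = c(genes$gene, paste0(genes$gene, ".cds")),
    Parent = c(rep(NA_character_, nrow(genes)), genes$gene),
    phase = c(rep(NA_integer_, nrow(genes)), rep(0L, nrow(genes))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a multi-sample VCF into a long genotype table
#'
#' Thin wrapper over `VariantAnnotation::readVcf` returning the long
#' format the genotyping module consumes (SNV records only).
#'
#' @param path VCF file.
#' @return data.table: chrom, pos, ref, sample, a1, a2, dp, gq.
#' @export
read_genotype_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = FALSE)
  vcf <- vcf[snv]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  gq <- VariantAnnotation::geno(vcf)$GQ
  ref <- as.character(rr$REF)
  altl <- lapply(rr$ALT, as.character)
  pos <- GenomicRanges::start(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  out <- lapply(colnames(gt), function(s) {
    parts <- strsplit(gt[, s], "[/|]")
    idx1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
    idx2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, character(1))))
    dealias <- function(idx, i) {
      if (is.na(idx)) return(NA_character_)
      if (idx == 0) ref[i] else altl[[i]][idx]
    }
    a1 <- vapply(seq_along(idx1), function(i) dealias(idx1[i], i), character(1))
    a2 <- vapply(seq_along(idx2), function(i) dealias(idx2[i], i), character(1))
    data.table::data.table(chrom = chrom, pos = pos, ref = ref, sample = s,
                           a1 = a1, a2 = a2,
                           dp = as.integer(dp[, s]), gq = as.integer(gq[, s]))
  })
  data.table::rbindlist(out)
}

#' Write haploid calls / window statistics as TSV
#' @param x A data.frame/data.table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Write window trees to a multi-tree newick file with window-index headers
#' @param trees List of `window_tree` objects.
#' @param path Output path; one newick per line, preceded by a comment line
#'   `# start end`.
#' @return Invisibly, `path`.
#' @export
write_window_trees <- function(trees, path) {
  lines <- unlist(lapply(trees, function(t)
    c(sprintf("# %s %s", format(t$start, scientific = FALSE),
              format(t$end, scientific = FALSE)),
      ape::write.tree(t$tree))))
  writeLines(lines, path)
  invisible(path)
}
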