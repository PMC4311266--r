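# Formats: minimal VCF 4.2 for genotypes, TSV for phenotypes/annotations/
# results, JSON for interchange containers and truth records. Interchange
# numerics are serialised at full precision (jsonlite digits = NA) so a
# write/read round trip preserves every numerical field.

#' Write a genotype matrix as minimal VCF 4.2
#'
#' CHROM, POS, ID, REF, ALT, QUAL=., FILTER=PASS, INFO=., FORMAT=GT with
#' unphased "/" genotypes; missing dosages become "./.".
#'
#' @param g a [genotype_matrix()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_vcf_minimal <- function(g, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  samples <- rownames(g$dosage)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- matrix(gt_code[g$dosage + 1L], nrow = nrow(g$dosage))
  gt[is.na(g$dosage)] <- "./."
  records <- vapply(seq_len(ncol(g$dosage)), function(j) {
    paste(c(g$variants$chrom[j], g$variants$pos[j], g$variants$id[j],
            g$variants$ref[j], g$variants$alt[j], ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a minimal diploid VCF into a genotype matrix
#'
#' Accepts VCF 4.2 with biallelic records and diploid GT fields; "0/1" and
#' phased "0|1" both count one alternate allele (phase is ignored at this
#' layer), "./." is missing. Multiallelic records and malformed genotypes
#' are rejected with the offending line number and position.
#'
#' @param path VCF file
#' @return a [genotype_matrix()] with ALT-allele dosages
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1)
    glyrare_stop("glyrare_malformed_vcf", "missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body_idx <- which(seq_along(lines) > hdr & !startsWith(lines, "#") &
                      nzchar(lines))
  n <- length(samples); m <- length(body_idx)
  dosage <- matrix(NA_integer_, n, m, dimnames = list(samples, NULL))
  variants <- data.frame(chrom = character(m), pos = integer(m),
                         id = character(m), ref = character(m),
                         alt = character(m), stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t")[[1]]
    if (length(f) != 9 + n)
      glyrare_stop("glyrare_malformed_vcf",
                   sprintf("line %d: expected %d fields, found %d", ln, 9 + n, length(f)))
    if (grepl(",", f[5], fixed = TRUE))
      glyrare_stop("glyrare_multiallelic",
                   sprintf("line %d (%s:%s): multiallelic records are not supported",
                           ln, f[1], f[2]))
    if (!startsWith(f[9], "GT"))
      glyrare_stop("glyrare_malformed_vcf",
                   sprintf("line %d: FORMAT must begin with GT", ln))
    gt <- sub(":.*", "", f[-(1:9)])
    alleles <- strsplit(gt, "[/|]")
    d <- vapply(alleles, function(a) {
      if (length(a) != 2) return(-2L)
      if (any(a == ".")) return(NA_integer_)
      ai <- suppressWarnings(as.integer(a))
      if (anyNA(ai) || any(ai > 1L)) return(-2L)
      sum(ai)
    }, integer(1))
    if (any(!is.na(d) & d == -2L))
      glyrare_stop("glyrare_malformed_vcf",
                   sprintf("line %d (%s:%s): malformed diploid GT field", ln, f[1], f[2]))
    dosage[, k] <- d
    variants[k, ] <- list(f[1], as.integer(f[2]), f[3], f[4], f[5])
  }
  genotype_matrix(dosage, variants)
}

#' Write / read tab-delimited phenotype or annotation tables
#' @param x data.frame
#' @param path file path
#' @return the path (write) or a data.frame (read)
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Score-set JSON interchange
#'
#' The documented container crossing the cohort/meta boundary: gene,
#' variant table, score vector U, covariance V (row-major), sample size,
#' trait kind and cohort label, at full numeric precision.
#'
#' @param s a [score_stats()] result
#' @param path JSON file
#' @return the path (write) or a `score_set` (read)
#' @export
write_score_set <- function(s, path) {
  payload <- list(gene = s$gene,
                  variants = s$variants,
                  U = unname(s$U),
                  V = as.vector(t(s$V)),
                  n = s$n, trait_kind = s$trait_kind, cohort = s$cohort)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_score_set
#' @export
read_score_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- length(x$U)
  V <- matrix(x$V, m, m, byrow = TRUE,
              dimnames = list(x$variants$id, x$variants$id))
  structure(list(gene = x$gene, variants = as.data.frame(x$variants),
                 U = stats::setNames(x$U, x$variants$id), V = V,
                 n = x$n, trait_kind = x$trait_kind, cohort = x$cohort),
            class = "score_set")
}

#' Haplotype-fit JSON interchange
#'
#' The haplotype analogue of the score-set container: labels, reference,
#' effect estimates with covariance (row-major), sample size and EM
#' frequencies.
#'
#' @param f a [fit_hap_model()] result
#' @param path JSON file
#' @return the path (write) or a `haplotype_fit` (read)
#' @export
write_hap_fit <- function(f, path) {
  payload <- list(cohort = f$cohort, reference = f$reference,
                  labels = names(f$gamma),
                  gamma = unname(f$gamma),
                  vcov = as.vector(t(f$vcov)),
                  freq_labels = names(f$frequencies),
                  frequencies = unname(f$frequencies),
                  sigma2 = f$sigma2, sigma2_b = f$sigma2_b,
                  dropped = f$dropped, n = f$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_hap_fit
#' @export
read_hap_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(x$gamma)
  structure(list(cohort = x$cohort, reference = x$reference,
                 gamma = stats::setNames(x$gamma, x$labels),
                 vcov = matrix(x$vcov, k, k, byrow = TRUE,
                               dimnames = list(x$labels, x$labels)),
                 beta_covar = NULL,
                 sigma2 = x$sigma2, sigma2_b = x$sigma2_b,
                 frequencies = stats::setNames(x$frequencies, x$freq_labels),
                 dropped = as.character(x$dropped %||% character(0)),
                 n = x$n),
            class = "haplotype_fit")
}
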