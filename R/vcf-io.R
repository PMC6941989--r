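#' Read a VCF into a genotype matrix
#'
#' Parses a VCFv4.x file (via \pkg{vcfR}), keeping biallelic SNP records
#' only; multiallelic and indel records are skipped and their count
#' reported with a message. Phase is preserved when every retained call
#' uses the `|` separator.
#'
#' @param path path to a VCF file (plain text or gzipped)
#' @param region optional `list(chrom=, start=, end=)` 1-based inclusive
#'   query; sites outside are dropped (an empty result is not an error).
#' @return a `genotype_matrix`
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no data lines")
  gt_field <- v@gt
  if (is.null(gt_field) || !"FORMAT" %in% colnames(gt_field))
    stop("VCF has no genotype (GT) columns")

  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  fix <- fix[snp, , drop = FALSE]
  gt_field <- gt_field[snp, , drop = FALSE]

  if (!all(grepl("^GT(:|$)", gt_field[, "FORMAT"])))
    stop("GT must be the first FORMAT field")
  gt <- gt_field[, setdiff(colnames(gt_field), "FORMAT"), drop = FALSE]
  gt[is.na(gt)] <- "./."
  gt <- sub(":.*$", "", gt)

  ids <- colnames(gt)
  pos <- as.integer(fix$POS)
  o <- order(fix$CHROM, pos)
  fix <- fix[o, , drop = FALSE]; pos <- pos[o]
  gt <- gt[o, , drop = FALSE]

  if (!is.null(region)) {
    keep <- fix$CHROM == region$chrom & pos >= region$start &
      pos <= region$end
    fix <- fix[keep, , drop = FALSE]; pos <- pos[keep]
    gt <- gt[keep, , drop = FALSE]
  }

  sites <- tibble(chrom = fix$CHROM, pos = pos, ref = fix$REF,
                  alt = fix$ALT)
  n_site <- nrow(sites); n_ind <- length(ids)
  if (n_site == 0) {
    empty <- matrix(integer(0), n_ind, 0, dimnames = list(ids, NULL))
    return(genotype_matrix(empty, sites))
  }

  a1 <- substr(gt, 1, 1); sep <- substr(gt, 2, 2); a2 <- substr(gt, 3, 3)
  miss <- a1 == "." | a2 == "." | gt %in% c("", ".")
  h1 <- suppressWarnings(as.integer(a1)); h2 <- suppressWarnings(as.integer(a2))
  h1[miss] <- NA_integer_; h2[miss] <- NA_integer_
  dos <- h1 + h2
  calls <- matrix(dos, n_site, n_ind, dimnames = list(NULL, ids))
  calls <- t(calls)
  phased <- all(sep[!miss] == "|") && any(!miss)
  if (phased) {
    hap_a <- t(matrix(h1, n_site, n_ind)); hap_b <- t(matrix(h2, n_site, n_ind))
    rownames(hap_a) <- rownames(hap_b) <- ids
    # phase carries no information at missing calls; dosage stays NA
    hap_a[is.na(calls)] <- 0L; hap_b[is.na(calls)] <- 0L
    genotype_matrix(calls, sites, hap_a, hap_b)
  } else {
    genotype_matrix(calls, sites)
  }
}

#' Write a genotype matrix as plain-text VCFv4.2
#'
#' Phased matrices are written with `|` genotype separators, unphased with
#' `/`; missing calls become `./.`.
#'
#' @param g a `genotype_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path) {
  ids <- individuals(g)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=supergene",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  n_site <- ncol(g$calls)
  if (n_site == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  sep <- if (g$phased) "|" else "/"
  if (g$phased) {
    gt <- matrix(paste0(t(g$hap_a), sep, t(g$hap_b)), n_site,
                 length(ids))
  } else {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix(code[t(g$calls) + 1L], n_site, length(ids))
  }
  gt[t(is.na(g$calls))] <- paste0(".", sep, ".")
  lines <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                 ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read / write a sample table (TSV)
#'
#' @param path TSV with columns `individual`, `species`, `morph`
#'   (and optionally `locus_class`)
#' @return a tibble
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "species", "morph") %in% names(df)))
  if (!"locus_class" %in% names(df)) df$locus_class <- NA
  as_tibble(df)
}

#' @rdname read_sample_table
#' @param samples a sample-table tibble
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export windows as BED (0-based half-open)
#'
#' @param windows a window tibble (`chrom`, `start`, `end`, ...)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_windows_bed <- function(windows, path) {
  utils::write.table(
    data.frame(windows$chrom, windows$start - 1L, windows$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
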