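# Plain-text I/O: minimal biallelic VCF (GT only), TSV dosage matrices,
# and the tab-separated kernel matrix format.

#' Write genotypes to VCF or TSV
#'
#' VCF dialect: VCFv4.2, biallelic SNPs, GT-only FORMAT, unphased diploid
#' genotypes (dosage = count of the ALT allele). TSV: animals in rows,
#' first column `animal_id`, remaining columns one per SNP.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  format <- match.arg(format, c("vcf", "tsv"))
  dos <- G$dosages
  if (format == "tsv") {
    df <- data.frame(animal_id = rownames(dos), dos, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  pos <- G$positions
  if (is.null(pos))
    pos <- data.frame(chrom = 1L, bp = seq_len(ncol(dos)))
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(dos)), function(j) {
    paste(c(pos$chrom[j], pos$bp[j], colnames(dos)[j], "A", "B", ".", "PASS",
            ".", "GT", gt[dos[, j] + 1L]), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF or TSV
#'
#' Reads the formats written by [write_genotypes()]. Multi-allelic VCF
#' records are skipped with a reported count. Missing genotypes either fail
#' (default) or are imputed to the per-SNP modal dosage.
#'
#' @param path input file path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @param missing `"fail"` (default) or `"impute"` (per-SNP mode).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = NULL, missing = c("fail", "impute")) {
  missing <- match.arg(missing)
  if (is.null(format))
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  format <- match.arg(format, c("vcf", "tsv"))
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    dos <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(matrix(!(dos %in% c("0", "1", "2")), nrow(dos)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-{0,1,2} entry '", dos[bad[1, 1], bad[1, 2]],
           "' at animal row ", bad[1, 1], ", SNP column '",
           colnames(dos)[bad[1, 2]], "'")
    storage.mode(dos) <- "integer"
    rownames(dos) <- df[[1]]
    return(genotype_matrix(dos))
  }
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("malformed VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  animals <- cols[-(1:9)]
  rows <- lines[(hdr + 1):length(lines)]
  rows <- rows[nzchar(rows)]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  multi <- vapply(fields, function(f) grepl(",", f[5], fixed = TRUE), logical(1))
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  fields <- fields[!multi]
  if (length(fields) == 0) stop("no biallelic records in VCF")
  n <- length(animals); m <- length(fields)
  dos <- matrix(NA_integer_, n, m)
  snp <- character(m); chrom <- character(m); bp <- numeric(m)
  for (j in seq_len(m)) {
    f <- fields[[j]]
    chrom[j] <- f[1]; bp[j] <- as.numeric(f[2]); snp[j] <- f[3]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stop("record ", snp[j], " has no GT field")
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, character(1), gti)
    al <- strsplit(gt, "[/|]")
    d <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
    if (anyNA(d)) {
      if (missing == "fail")
        stop("missing GT at SNP ", snp[j],
             " (set missing = \"impute\" to impute to the mode)")
      md <- as.integer(names(which.max(table(d))))
      d[is.na(d)] <- md
    }
    dos[, j] <- d
  }
  rownames(dos) <- animals; colnames(dos) <- snp
  genotype_matrix(dos, positions = data.frame(chrom = chrom, bp = bp))
}

#' Write a kernel to the tab-separated matrix format
#'
#' First row: animal IDs; subsequent rows: animal ID followed by the n matrix
#' entries at 12 significant digits (the format round-trips to that
#' precision).
#'
#' @param K a `grm` kernel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(K)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  for (i in seq_len(nrow(K)))
    writeLines(paste(c(ids[i], formatC(unclass(K)[i, ], format = "g", digits = 12)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a kernel from the tab-separated matrix format
#'
#' @param path input file path.
#' @param name kernel name to attach.
#' @return A `grm` kernel.
#' @export
read_kernel <- function(path, name = "K") {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    stopifnot(f[1] == ids[i])
    M[i, ] <- as.numeric(f[-1])
  }
  .new_grm((M + t(M)) / 2, name)
}
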