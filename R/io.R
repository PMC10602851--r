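## Cheap deterministic polynomial hash of a string, for output provenance
## headers (not cryptographic).
configHash <- function(s) {
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Write a table with a provenance header comment
#'
#' Writes tab-delimited output preceded by \code{# key=value} comment
#' lines (typically the run seed and config hash), readable back with
#' \code{\link{readTsv}}.
#'
#' @param x data.frame
#' @param path output path
#' @param meta named character vector written as header comments
#' @export
writeTsv <- function(x, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, "=", meta[[k]]), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeTsv
#' @return \code{readTsv}: the data.frame (comment lines skipped)
#' @export
readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write per-strain variants as a VCF v4.2 file
#'
#' Positions are 1-based; indel records share the anchor base between REF
#' and ALT. The strain is recorded in the INFO field (\code{STRAIN=}).
#'
#' @param variants a \linkS4class{VariantTable}
#' @param path output path
#' @param contigLengths optional named chromosome lengths for the header
#' @export
writeVariantVcf <- function(variants, path, contigLengths = NULL) {
  v <- variantRecords(variants)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines('##INFO=<ID=STRAIN,Number=1,Type=String,Description="Strain carrying the ALT allele">',
             con)
  for (ch in names(contigLengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(contigLengths[[ch]])), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(v))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSTRAIN=%s",
                       v$chrom, v$pos, v$ref, v$alt, v$strain), con)
}

#' Read a VCF of per-strain variants
#'
#' Reads a plain-text VCF (via vcfR) into a \linkS4class{VariantTable},
#' taking the strain from the \code{STRAIN=} INFO key (or the
#' \code{strain} argument when absent).
#'
#' @param path VCF path
#' @param strain fallback strain label
#' @return a \linkS4class{VariantTable}
#' @export
readVariantVcf <- function(path, strain = "strain") {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(vcf) || nrow(vcf@fix) == 0) return(VariantTable())
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  st <- ifelse(grepl("STRAIN=", info),
               sub(".*STRAIN=([^;]+).*", "\\1", info), strain)
  VariantTable(data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT, strain = st))
}

readPeaksBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

writePeaksBed <- function(peaks, path) {
  if (is.null(names(peaks))) names(peaks) <- paste0("peak", seq_along(peaks))
  rtracklayer::export(peaks, path, format = "BED")
}

readCountsTsv <- function(path) {
  d <- readTsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

writeCountsTsv <- function(counts, path, meta = character()) {
  writeTsv(data.frame(feature_id = rownames(counts), counts,
                      check.names = FALSE), path, meta)
}
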