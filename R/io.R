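#' Read a genotype panel from VCF or dosage TSV
#'
#' VCF: biallelic SNPs with a `GT` field; the dosage is the count of
#' alternate alleles (`0/1` and `0|1` both give 1; `./.` gives missing).
#' Multi-allelic records are rejected with their ids listed. Dosage TSV:
#' a tab-separated table whose header is `id` followed by SNP ids, one
#' individual per row, values in `{0, 1, 2, NA}` (real values allowed for
#' imputed dosages), accompanied by a map TSV with columns
#' `snp`, `chrom`, `pos`.
#'
#' @param path VCF or dosage-TSV file.
#' @param format `"vcf"` or `"dosage_tsv"` (guessed from the extension by
#'   default).
#' @param mapPath map TSV for `dosage_tsv` input; defaults to
#'   `<path-without-extension>.map.tsv`.
#' @return a [GenotypePanel-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                          mapPath = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  }
  if (format == "vcf") .readVcfPanel(path) else .readDosageTsv(path, mapPath)
}

.readVcfPanel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    stop(sprintf("multi-allelic record(s) not supported: %s",
                 paste(utils::head(fix[multi, "ID"], 10), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(x)
             sum(suppressWarnings(as.numeric(x))), numeric(1)))
  }
  d <- apply(gt, 2, alleles)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, names(d)))
  d <- t(d)  # individuals x SNPs
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix[, "CHROM"], fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicated SNP ids in VCF")
  colnames(d) <- ids
  GenotypePanel(d, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

.readDosageTsv <- function(path, mapPath = NULL) {
  if (is.null(mapPath)) mapPath <- paste0(sub("\\.tsv$", "", path), ".map.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (names(tab)[1] != "id") stop("dosage TSV must start with an 'id' column")
  if (anyDuplicated(tab$id)) stop("duplicated individual ids in dosage TSV")
  d <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(d)) stop("non-numeric dosage values")
  rownames(d) <- tab$id
  map <- utils::read.table(mapPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("snp", "chrom", "pos") %in% names(map)))
    stop("map TSV must have columns snp, chrom, pos")
  miss <- setdiff(colnames(d), map$snp)
  if (length(miss)) stop(sprintf("SNP(s) missing from map: %s",
                                 paste(utils::head(miss, 5), collapse = ", ")))
  map <- map[match(colnames(d), map$snp), ]
  GenotypePanel(d, chrom = map$chrom, pos = map$pos)
}

#' Write a genotype panel
#'
#' `dosage_tsv` writes the canonical exchange format (dosage table plus
#' `.map.tsv` sidecar); `vcf` writes a minimal VCF 4.2 with GT genotypes
#' (hard dosages only; imputed real-valued dosages are rounded). A header
#' comment names the producing stage.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix output path prefix (extensions are appended).
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return invisibly, the paths written.
#' @export
writeGenotypes <- function(panel, prefix, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  if (format == "dosage_tsv") {
    dosPath <- paste0(prefix, ".tsv")
    mapPath <- paste0(prefix, ".map.tsv")
    con <- file(dosPath, "w")
    writeLines(c("# aquaGS dosage panel",
                 paste(c("id", colnames(d)), collapse = "\t")), con)
    utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    close(con)
    utils::write.table(cbind(snp = colnames(d), chrom = panel@chrom,
                             pos = panel@pos),
                       mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(dosPath, mapPath))
  } else {
    path <- paste0(prefix, ".vcf")
    gtcode <- c("0/0", "0/1", "1/1")
    dr <- round(d)
    lines <- c("##fileformat=VCFv4.2",
               "##source=aquaGS",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t"))
    body <- vapply(seq_len(ncol(d)), function(j) {
      gt <- ifelse(is.na(dr[, j]), "./.", gtcode[dr[, j] + 1])
      paste(c(panel@chrom[j], panel@pos[j], colnames(d)[j], "A", "G", ".",
              "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
    invisible(path)
  }
}

#' Read a phenotype table
#'
#' Tab-separated, header row, first column `id`, remaining columns numeric
#' traits (`NA` allowed). Reports a per-trait summary (mean and SD).
#'
#' @param path phenotype TSV.
#' @return data.frame with attribute `"summary"` (trait mean/SD table).
#' @export
readPhenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (names(tab)[1] != "id") stop("phenotype TSV must start with an 'id' column")
  for (j in seq_along(tab)[-1]) {
    raw <- tab[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num) & raw != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric phenotype value at row %d, column '%s'",
                   bad[1], names(tab)[j]))
    }
    tab[[j]] <- num
  }
  attr(tab, "summary") <- data.frame(
    trait = names(tab)[-1],
    mean = vapply(tab[-1], mean, numeric(1), na.rm = TRUE),
    sd = vapply(tab[-1], stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  tab
}

#' Match phenotypes to a genotype panel
#'
#' Intersects phenotype rows with panel individuals by exact id; rows
#' without genotypes are dropped with a warning (and counted in the
#' `"nUnmatched"` attribute).
#'
#' @param panel a [GenotypePanel-class].
#' @param phenotypes data.frame from [readPhenotypes()].
#' @return the matched phenotype data.frame, panel order.
#' @export
matchPhenotypes <- function(panel, phenotypes) {
  ids <- intersect(individualIds(panel), phenotypes$id)
  if (!length(ids)) stop("no overlapping individual ids between phenotypes and genotypes")
  dropped <- setdiff(phenotypes$id, ids)
  if (length(dropped)) {
    warning(sprintf("%d phenotyped individual(s) without genotypes dropped",
                    length(dropped)))
  }
  out <- phenotypes[match(ids, phenotypes$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nUnmatched") <- length(dropped)
  out
}

#' Write / read a GRM as TSV with a JSON sidecar
#'
#' The TSV has a header row of ids and an id column; the JSON sidecar
#' carries the VanRaden denominator and dimensions.
#'
#' @param grm a [GRM-class].
#' @param prefix path prefix.
#' @return invisibly, the paths written.
#' @export
writeGrm <- function(grm, prefix) {
  stopifnot(is(grm, "GRM"))
  v <- as.matrix(grm)
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(data.frame(id = rownames(v), v, check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(n = nrow(v), denominator = grm@denominator),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' @rdname writeGrm
#' @param prefix path prefix used by [writeGrm()].
#' @return `readGrm`: a [GRM-class].
#' @export
readGrm <- function(prefix) {
  tab <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab$id
  v <- (v + t(v)) / 2
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  new("GRM", values = v, denominator = as.numeric(meta$denominator),
      alleleFreqs = numeric())
}
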