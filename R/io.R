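#' Read a SNP effect table
#'
#' Reads a GWAS-summary-statistics-style TSV with header
#' `rsid chrom pos risk_allele other_allele or p source`. Duplicated rsids
#' are allowed (they are pooled later by [meta_dedupe()]).
#'
#' @param path TSV file path.
#' @return data.frame of SNP effects.
#' @export
read_effect_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("rsid", "chrom", "pos", "risk_allele", "other_allele",
            "or", "p", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("effect table ", path, " missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a panel (or effect table) as TSV
#'
#' @param panel a `prs_panel` or a SNP effect data.frame.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  df <- if (inherits(panel, "prs_panel")) panel$snps else panel
  df <- df[c("rsid", "chrom", "pos", "risk_allele", "other_allele",
             "or", "p", "source")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel TSV
#'
#' @param path TSV path with the effect-table header.
#' @param hla_tag rsid of the HLA tag SNP, or `NULL`.
#' @return a `prs_panel`.
#' @export
read_panel <- function(path, hla_tag = NULL) {
  prs_panel(read_effect_table(path), hla_tag = hla_tag)
}

#' Write a dosage matrix as plain TSV
#'
#' Rows are individuals (first column `id`), remaining columns one per SNP
#' named by rsid.
#'
#' @param dm a `dosage_matrix`.
#' @param path output path.
#' @export
write_dosage_tsv <- function(dm, path) {
  df <- data.frame(id = rownames(dm$dosages), dm$dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from plain TSV
#'
#' @param path TSV path as written by [write_dosage_tsv()].
#' @param snp_info SNP metadata data.frame (see [dosage_matrix()]); if `NULL`,
#'   minimal metadata with unknown positions/alleles is synthesised.
#' @param cohort cohort label.
#' @return a `dosage_matrix`.
#' @export
read_dosage_tsv <- function(path, snp_info = NULL, cohort = "cohort") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df$id
  m <- as.matrix(df[setdiff(names(df), "id")])
  if (is.null(snp_info)) {
    snp_info <- data.frame(rsid = colnames(m), chrom = NA_character_,
                           pos = NA_integer_, risk_allele = NA_character_,
                           other_allele = NA_character_)
  } else {
    snp_info <- snp_info[match(colnames(m), snp_info$rsid), , drop = FALSE]
    if (anyNA(snp_info$rsid)) stop("snp_info does not cover all TSV columns")
  }
  dosage_matrix(m, snp_info, cohort, individual_ids = ids)
}

#' Write a dosage matrix as VCF 4.2 with a DS FORMAT field
#'
#' One record per SNP; genotypes are omitted and only the dosage (`DS`,
#' expected count of the ALT allele, which is the panel's risk allele) is
#' emitted, matching imputed-dosage VCF conventions.
#'
#' @param dm a `dosage_matrix`.
#' @param path output path (plain text `.vcf`).
#' @export
write_vcf_ds <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dm$dosages)), collapse = "\t")
  ), con)
  si <- dm$snp_info
  for (j in seq_len(ncol(dm$dosages))) {
    writeLines(paste(c(si$chrom[j], si$pos[j], si$rsid[j],
                       si$other_allele[j], si$risk_allele[j],
                       ".", "PASS", ".", "DS",
                       formatC(dm$dosages[, j], format = "g", digits = 6)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Parses a plain-text VCF 4.2 file as written by [write_vcf_ds()] (the `DS`
#' field may sit at any position in FORMAT). The ALT allele is taken as the
#' counted (risk) allele.
#'
#' @param path VCF path.
#' @param cohort cohort label.
#' @return a `dosage_matrix`.
#' @export
read_vcf_ds <- function(path, cohort = "cohort") {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no variant records in ", path)
  recs <- strsplit(body, "\t", fixed = TRUE)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(recs))
  si <- data.frame(rsid = character(length(recs)), chrom = "",
                   pos = 0L, risk_allele = "", other_allele = "")
  for (j in seq_along(recs)) {
    r <- recs[[j]]
    fmt <- strsplit(r[9], ":", fixed = TRUE)[[1]]
    k <- match("DS", fmt)
    if (is.na(k)) stop("record ", r[3], " has no DS field")
    vals <- vapply(strsplit(r[-(1:9)], ":", fixed = TRUE),
                   function(f) as.numeric(f[k]), numeric(1))
    m[, j] <- vals
    si$rsid[j] <- r[3]; si$chrom[j] <- r[1]; si$pos[j] <- as.integer(r[2])
    si$other_allele[j] <- r[4]; si$risk_allele[j] <- r[5]
  }
  dosage_matrix(m, si, cohort, individual_ids = ids)
}

#' Write a phenotype/covariate table as TSV
#'
#' Header `id status age sex pc1 pc2`, `status` in `{0,1}`, `sex` in `{F,M}`.
#'
#' @param tab cohort table (see [cohort_table()]).
#' @param path output path.
#' @export
write_phenotypes <- function(tab, path) {
  tab <- cohort_table(tab)[c("id", "status", "age", "sex", "pc1", "pc2")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#' @param path TSV path as written by [write_phenotypes()].
#' @return a validated cohort table.
#' @export
read_phenotypes <- function(path) {
  cohort_table(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Read a prevalence table
#'
#' TSV with header `population prevalence_per_1e5 population_size`.
#'
#' @param path TSV path.
#' @return data.frame of prevalence records.
#' @export
read_prevalence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("population", "prevalence_per_1e5", "population_size")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("prevalence table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$prevalence_per_1e5 <= 0 | df$prevalence_per_1e5 >= 1e5)) {
    stop("prevalence_per_1e5 must lie in (0, 100000)")
  }
  df
}
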