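#' Write the per-subject phenotype table
#'
#' Tab-delimited, one row per subject, single header row. Columns: `id`,
#' `age`, `bmi`, `ohd` (empty when unmeasured), then `event_<endpoint>` and
#' `time_<endpoint>` for every endpoint present. Genotype columns are
#' deliberately excluded (they travel in the VCF / genotype matrix).
#'
#' @param cohort A `cohort_table` from [simulate_cohort()] (or any data frame
#'   with the same columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  cols <- c("id", "age", "bmi", "ohd",
            as.vector(rbind(paste0("event_", ENDPOINTS),
                            paste0("time_", ENDPOINTS))))
  cols <- intersect(cols, names(cohort))
  utils::write.table(cohort[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path File path.
#' @return Data frame with `id` as character and empty 25OHD read as `NA`.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "",
                    colClasses = c(id = "character"),
                    stringsAsFactors = FALSE)
}

#' Write genotypes as a minimal VCF 4.2
#'
#' Five records (one per panel SNP) and one sample column per subject.
#' Hard-called SNPs carry a `GT` field (`0/0`, `0/1`, `1/1` counting the
#' higher-25OHD allele as ALT); imputed SNPs carry a `DS` dosage field.
#' Chromosome and position are synthetic placeholders (the panel is defined
#' by rsid, not coordinates).
#'
#' @param allele_counts Integer `n x 5` matrix from [draw_genotypes()].
#' @param dosages Numeric `n x 5` matrix from [add_imputation_noise()]; used
#'   for SNPs flagged imputed.
#' @param snps The SNP panel.
#' @param path Output file path.
#' @param ids Optional subject IDs (default `S000001`, ...).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(allele_counts, dosages, snps = default_snp_panel(),
                      path, ids = NULL) {
  n <- nrow(allele_counts)
  stopifnot(identical(dim(allele_counts), dim(dosages)))
  if (is.null(ids)) ids <- sprintf("S%06d", seq_len(n))
  imputed <- panel_field(snps, "imputed")
  rsids <- panel_rsids(snps)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vitdmr synthetic cohort generator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Imputed dosage of the ALT (higher-25OHD) allele\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  records <- vapply(seq_along(rsids), function(j) {
    if (imputed[j]) {
      fmt <- "DS"
      vals <- sprintf("%.4g", dosages[, j])
    } else {
      fmt <- "GT"
      vals <- gt_code[allele_counts[, j] + 1L]
    }
    paste(c("1", as.character(1000L * j), rsids[j], "A", "G", ".", "PASS",
            ".", fmt, vals), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read panel genotypes from a VCF or delimited matrix
#'
#' VCF input (`.vcf`) is parsed with \pkg{vcfR}; `GT` records become hard
#' allele counts and `DS` records dosages. Delimited input is a
#' tab-separated matrix with an `id` column and one column per rsid.
#' Dosage columns are returned as-is — apply [round_dosage()] (or
#' [grs_table()], which does it for you) before scoring.
#'
#' @param path Input file.
#' @param snps The SNP panel the columns/records are validated against.
#' @return List with `id` (character) and `genotypes` (`n x 5` numeric
#'   matrix, columns in panel order).
#' @export
read_genotypes <- function(path, snps = default_snp_panel()) {
  rsids <- panel_rsids(snps)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ids <- colnames(v@gt)[-1]
    found <- v@fix[, "ID"]
    missing <- setdiff(rsids, found)
    if (length(missing)) {
      stop("VCF is missing panel SNPs: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    geno <- sapply(rsids, function(rs) {
      i <- match(rs, found)
      fmt <- strsplit(v@gt[i, 1], ":", fixed = TRUE)[[1]]
      if ("DS" %in% fmt) {
        as.numeric(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)[i, ])
      } else {
        gt <- vcfR::extract.gt(v, element = "GT")[i, ]
        vapply(strsplit(gt, "[/|]"), function(a) sum(a == "1"), numeric(1))
      }
    })
    geno <- matrix(geno, ncol = length(rsids),
                   dimnames = list(NULL, rsids))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    missing <- setdiff(rsids, names(tab))
    if (length(missing)) {
      stop("genotype table is missing panel SNPs: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ids <- if ("id" %in% names(tab)) as.character(tab$id)
           else as.character(seq_len(nrow(tab)))
    geno <- as.matrix(tab[, rsids])
  }
  list(id = ids, genotypes = geno)
}

#' Write genotypes as a delimited matrix
#'
#' Tab-separated companion format to the VCF: an `id` column plus one
#' numeric column per rsid (hard counts for genotyped SNPs, dosages for
#' imputed ones).
#'
#' @inheritParams write_vcf
#' @export
write_genotype_table <- function(allele_counts, dosages,
                                 snps = default_snp_panel(), path,
                                 ids = NULL) {
  n <- nrow(allele_counts)
  if (is.null(ids)) ids <- sprintf("S%06d", seq_len(n))
  imputed <- panel_field(snps, "imputed")
  out <- as.data.frame(ifelse(matrix(imputed, n, length(imputed),
                                     byrow = TRUE),
                              dosages, allele_counts))
  names(out) <- panel_rsids(snps)
  utils::write.table(cbind(id = ids, out), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generator configuration to a YAML file
#'
#' Every scalar default is preserved; the SNP panel is written as a block per
#' variant. [read_generator_config()] round-trips the file back through
#' [generator_config()], so derived quantities (calibrated effects, hazards)
#' are re-solved on read rather than trusted from the file.
#'
#' @param config A [generator_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  snps <- lapply(config$snps, function(s) {
    s <- unclass(s)
    s$per_allele_effect <- NULL  # re-calibrated on read
    s
  })
  x <- list(
    n_cohort = config$n_cohort, n_subcohort = config$n_subcohort,
    ohd_mean = config$ohd_mean, ohd_sd = config$ohd_sd,
    target_r2 = config$target_r2,
    age_mean = config$age_mean, age_sd = config$age_sd,
    age_min = config$age_min,
    bmi_mean = config$bmi_mean, bmi_sd = config$bmi_sd,
    bmi_min = config$bmi_min,
    followup_years = config$followup_years,
    noise_sd = config$noise_sd,
    reference_n = config$reference_n,
    seed = config$seed,
    snps = snps,
    endpoints = lapply(stats::setNames(ENDPOINTS, ENDPOINTS), function(e) {
      list(target_events = unname(config$target_events[[e]]),
           causal_log_hr_per_nmol =
             unname(config$causal_log_hr_per_nmol[[e]]),
           age_log_hr = unname(config$age_log_hr[[e]]))
    })
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a generator configuration from a YAML file
#' @param path File written by [write_generator_config()] (or hand-edited).
#' @param seed Optional seed overriding the one in the file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path, seed = NULL) {
  x <- yaml::read_yaml(path)
  snps <- lapply(x$snps, function(s) {
    snp_definition(s$rsid, s$gene, s$maf,
                   if (is.null(s$per_allele_effect)) NA_real_
                   else s$per_allele_effect,
                   isTRUE(s$imputed), isTRUE(s$risk_allele_is_minor))
  })
  pull <- function(field) {
    vapply(x$endpoints[ENDPOINTS], function(e) {
      v <- e[[field]]
      if (is.null(v)) 0 else as.numeric(v)
    }, numeric(1))
  }
  generator_config(
    n_cohort = x$n_cohort, n_subcohort = x$n_subcohort, snps = snps,
    ohd_mean = x$ohd_mean, ohd_sd = x$ohd_sd, target_r2 = x$target_r2,
    age_mean = x$age_mean, age_sd = x$age_sd, age_min = x$age_min,
    bmi_mean = x$bmi_mean, bmi_sd = x$bmi_sd, bmi_min = x$bmi_min,
    followup_years = x$followup_years,
    target_events = pull("target_events"),
    causal_log_hr_per_nmol = pull("causal_log_hr_per_nmol"),
    age_log_hr = pull("age_log_hr"),
    noise_sd = x$noise_sd,
    reference_n = if (is.null(x$reference_n)) 23294L else x$reference_n,
    seed = if (is.null(seed)) x$seed else seed
  )
}
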