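#' Define a 25OHD-associated SNP for simulation and scoring
#'
#' A SNP definition fixes the identity and generator truth for one of the
#' five vitamin D variants: its locus, minor allele frequency, the per-allele
#' effect on circulating 25OHD (nmol/L per copy of the higher-25OHD allele),
#' and whether its genotypes are imputed dosages rather than hard calls.
#'
#' The score convention orients every variant so that the counted allele is
#' the one associated with *higher* 25OHD; per-allele effects are therefore
#' constrained to be non-negative.
#'
#' @param rsid SNP identifier (e.g. `"rs2282679"`).
#' @param gene Gene label, one of `"DHCR7"`, `"CYP2R1"`, `"GC"`.
#' @param maf Allele frequency of the counted (higher-25OHD) allele, in
#'   `(0, 0.5]`.
#' @param per_allele_effect nmol/L increase in 25OHD per counted allele;
#'   `NA` means "to be solved by calibration" (see [calibrate_first_stage()]).
#' @param imputed Logical; `TRUE` if genotypes are imputed dosages in `[0, 2]`
#'   rather than hard calls.
#' @param risk_allele_is_minor Logical; `TRUE` when the counted
#'   (higher-25OHD) allele is the minor allele. For the default panel the
#'   minor alleles predict genetically *low* 25OHD, so the counted allele is
#'   the major one and its frequency is `1 - maf`.
#' @return An object of class `snp_definition` (a named list).
#' @seealso [default_snp_panel()]
#' @export
snp_definition <- function(rsid, gene, maf, per_allele_effect = NA_real_,
                           imputed = FALSE, risk_allele_is_minor = FALSE) {
  stopifnot(is.character(rsid), length(rsid) == 1L, nzchar(rsid))
  gene <- match.arg(gene, c("DHCR7", "CYP2R1", "GC"))
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("maf for ", rsid, " must lie in (0, 0.5], got ", format(maf),
         call. = FALSE)
  }
  if (!is.na(per_allele_effect) && per_allele_effect < 0) {
    stop("per_allele_effect for ", rsid,
         " must be >= 0 (alleles are oriented to higher 25OHD)",
         call. = FALSE)
  }
  structure(
    list(rsid = rsid, gene = gene, maf = as.numeric(maf),
         per_allele_effect = as.numeric(per_allele_effect),
         imputed = isTRUE(imputed),
         risk_allele_is_minor = isTRUE(risk_allele_is_minor)),
    class = "snp_definition"
  )
}

#' The default five-SNP vitamin D panel
#'
#' Two variants at the DHCR7 locus (7-dehydrocholesterol reductase), two at
#' CYP2R1 (hepatic 25-hydroxylase) and one at GC (vitamin D binding protein).
#' rs11234027 and rs7944926 are hard-called; rs10741657, rs12794714 and
#' rs2282679 are imputed dosages.
#'
#' Per-SNP minor allele frequencies are not published for the emulated cohort
#' (only the 16--44% range); the defaults are stand-ins chosen inside that
#' range and are fully configurable. For all five variants the minor allele
#' predicts genetically *low* 25OHD, so the counted (higher-25OHD) allele is
#' the major one with frequency `1 - maf`; this puts the mean score near 6.6
#' and populates the 0-5 / 6-7 / 8-10 categories in realistic proportions
#' (roughly 22/50/28%). Per-allele effects default to `NA` and are solved
#' jointly by [calibrate_first_stage()] so that the score explains the target
#' fraction of 25OHD variance.
#'
#' @param mafs Numeric vector of 5 allele frequencies, in panel order
#'   (rs11234027, rs12794714, rs10741657, rs7944926, rs2282679).
#' @return A list of 5 [snp_definition()] objects.
#' @export
default_snp_panel <- function(mafs = c(0.21, 0.42, 0.38, 0.40, 0.28)) {
  stopifnot(length(mafs) == 5L)
  list(
    snp_definition("rs11234027", "DHCR7",  mafs[1], imputed = FALSE),
    snp_definition("rs12794714", "CYP2R1", mafs[2], imputed = TRUE),
    snp_definition("rs10741657", "CYP2R1", mafs[3], imputed = TRUE),
    snp_definition("rs7944926",  "DHCR7",  mafs[4], imputed = FALSE),
    snp_definition("rs2282679",  "GC",     mafs[5], imputed = TRUE)
  )
}

#' @export
print.snp_definition <- function(x, ...) {
  cat(sprintf("<snp_definition> %s (%s): maf = %.3f, effect = %s nmol/L/allele%s\n",
              x$rsid, x$gene, x$maf,
              if (is.na(x$per_allele_effect)) "uncalibrated"
              else format(x$per_allele_effect, digits = 4),
              if (x$imputed) " [imputed]" else ""))
  invisible(x)
}

# internal: validate a panel and pull a field across SNPs
panel_field <- function(snps, field) {
  if (!is.list(snps) || length(snps) != 5L ||
      !all(vapply(snps, inherits, logical(1), "snp_definition"))) {
    stop("`snps` must be a list of exactly 5 snp_definition objects",
         call. = FALSE)
  }
  vapply(snps, `[[`, vector(mode = mode(snps[[1]][[field]]), length = 1L),
         field)
}

panel_rsids <- function(snps) panel_field(snps, "rsid")
panel_mafs  <- function(snps) panel_field(snps, "maf")

# frequency of the counted (higher-25OHD) allele per SNP
panel_counted_freqs <- function(snps) {
  maf <- panel_mafs(snps)
  minor <- panel_field(snps, "risk_allele_is_minor")
  ifelse(minor, maf, 1 - maf)
}
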