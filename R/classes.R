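#' Construct a site map
#'
#' A site map is the ordered table of variant records shared by every panel
#' and genotype matrix in a run: physical position, alleles, cumulative
#' genetic position and the site-class flags used downstream (array
#' ascertainment, exomic target, multi-mapping).
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based base-pair positions, strictly
#'   increasing.
#' @param id character vector of variant identifiers.
#' @param ref,alt allele strings; `ref != alt` at every site. Alleles longer
#'   than one base mark the record as an indel.
#' @param cm cumulative genetic position in centiMorgans, non-decreasing.
#' @param is_exomic,is_array,is_multimap logical flags per site. Default
#'   `FALSE` where not supplied.
#' @return A `data.frame` of class `site_map`, one row per site.
#' @export
site_map <- function(chrom, pos, id, ref, alt, cm,
                     is_exomic = FALSE, is_array = FALSE,
                     is_multimap = FALSE) {
  n <- length(pos)
  sm <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    id = as.character(id),
    ref = as.character(ref),
    alt = as.character(alt),
    cm = as.numeric(cm),
    is_exomic = rep_len(as.logical(is_exomic), n),
    is_array = rep_len(as.logical(is_array), n),
    is_multimap = rep_len(as.logical(is_multimap), n),
    stringsAsFactors = FALSE
  )
  validate_site_map(sm)
  class(sm) <- c("site_map", "data.frame")
  sm
}

validate_site_map <- function(sm) {
  # a zero-site map is valid (e.g. everything filtered by QC)
  if (nrow(sm) == 0) return(invisible(sm))
  if (any(diff(sm$pos) <= 0)) stop("site positions must be strictly increasing")
  if (any(diff(sm$cm) < 0)) stop("genetic positions must be non-decreasing")
  if (any(sm$ref == sm$alt)) stop("ref and alt alleles must differ")
  invisible(sm)
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("site_map: %d sites on %s, %d-%d bp, %.3f cM\n",
              nrow(x), x$chrom[1], min(x$pos), max(x$pos),
              max(x$cm) - min(x$cm)))
  cat(sprintf("  array sites: %d; exomic: %d; indels: %d; multimap: %d\n",
              sum(x$is_array), sum(x$is_exomic), sum(!is_snv(x)),
              sum(x$is_multimap)))
  invisible(x)
}

#' Single-nucleotide status of each site
#' @param sm a `site_map`.
#' @return Logical vector, `TRUE` where both alleles are single bases.
#' @export
is_snv <- function(sm) nchar(sm$ref) == 1L & nchar(sm$alt) == 1L

#' Construct a haplotype panel
#'
#' A phased reference panel: an `H x L` matrix of alleles (0 = ref, 1 = alt,
#' `NA` = missing) over a shared [site_map], with haplotypes optionally
#' paired into diploid subjects.
#'
#' @param alleles integer matrix, haplotypes in rows, sites in columns.
#' @param sm the `site_map` the columns refer to.
#' @param hap_ids character vector of haplotype identifiers (default
#'   `hap1..hapH`).
#' @param subject_ids character vector, one per haplotype, naming the diploid
#'   subject each haplotype belongs to (`NA` if unpaired). Subjects own
#'   exactly two haplotypes.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(alleles, sm, hap_ids = NULL, subject_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 1) stop("a haplotype panel needs at least one haplotype")
  if (ncol(alleles) != nrow(sm))
    stop("allele matrix has ", ncol(alleles), " sites but site map has ",
         nrow(sm))
  if (any(!is.na(alleles) & !(alleles %in% c(0L, 1L))))
    stop("panel alleles must be 0, 1 or NA")
  if (is.null(hap_ids)) hap_ids <- paste0("hap", seq_len(nrow(alleles)))
  if (is.null(subject_ids)) subject_ids <- rep(NA_character_, nrow(alleles))
  if (anyDuplicated(hap_ids)) stop("duplicated haplotype ids")
  structure(
    list(alleles = alleles, site_map = sm,
         hap_ids = as.character(hap_ids),
         subject_ids = as.character(subject_ids)),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  ns <- length(unique(stats::na.omit(x$subject_ids)))
  cat(sprintf("hap_panel: %d haplotypes (%d paired subjects) x %d sites\n",
              n_haps(x), ns, nrow(x$site_map)))
  invisible(x)
}

#' Number of haplotypes in a panel
#' @param panel a `hap_panel`.
#' @export
n_haps <- function(panel) nrow(panel$alleles)

#' Subset a haplotype panel by site or haplotype
#' @param panel a `hap_panel`.
#' @param sites integer or logical index over sites (columns).
#' @param haps integer or logical index over haplotypes (rows).
#' @return A `hap_panel` over the subset.
#' @export
subset_panel <- function(panel, sites = NULL, haps = NULL) {
  a <- panel$alleles
  sm <- panel$site_map
  hid <- panel$hap_ids
  sid <- panel$subject_ids
  if (!is.null(haps)) {
    a <- a[haps, , drop = FALSE]
    hid <- hid[haps]
    sid <- sid[haps]
  }
  if (!is.null(sites)) {
    a <- a[, sites, drop = FALSE]
    sm <- sm[sites, , drop = FALSE]
    class(sm) <- c("site_map", "data.frame")
  }
  hap_panel(a, sm, hid, sid)
}

#' Diploid genotype dosages implied by a panel's haplotype pairs
#'
#' Sums each subject's two haplotypes into 0/1/2 genotypes.
#'
#' @param panel a `hap_panel` whose haplotypes are paired into subjects.
#' @return Integer matrix, subjects in rows (named), sites in columns.
#' @export
panel_genotypes <- function(panel) {
  subj <- unique(stats::na.omit(panel$subject_ids))
  if (length(subj) == 0) stop("panel has no paired subjects")
  g <- t(vapply(subj, function(s) {
    rows <- which(panel$subject_ids == s)
    if (length(rows) != 2)
      stop("subject ", s, " has ", length(rows), " haplotypes, expected 2")
    colSums(panel$alleles[rows, , drop = FALSE])
  }, numeric(ncol(panel$alleles))))
  storage.mode(g) <- "integer"
  rownames(g) <- subj
  g
}

#' Allele frequencies in a haplotype panel
#' @param panel a `hap_panel`.
#' @param minor fold to the minor allele frequency (default `FALSE`:
#'   alternate-allele frequency).
#' @return Numeric vector, one frequency per site (`NaN` where all missing).
#' @export
panel_freq <- function(panel, minor = FALSE) {
  f <- colMeans(panel$alleles, na.rm = TRUE)
  if (minor) f <- pmin(f, 1 - f)
  f
}

#' Construct a diploid genotype matrix with call-level qualities
#'
#' The container for "called" genotype data: per-subject, per-site calls in
#' `{0, 1, 2, NA}`, phred-scaled per-call genotype qualities (GQ) and a
#' phred-scaled per-site quality (QUAL).
#'
#' @param calls integer matrix, subjects in rows, sites in columns.
#' @param sm the `site_map` the columns refer to.
#' @param gq numeric matrix of phred-scaled call qualities, same shape as
#'   `calls`.
#' @param site_qual numeric vector of phred-scaled site qualities, one per
#'   site.
#' @param subjects character vector of subject ids (default taken from
#'   `rownames(calls)`).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, sm, gq = NULL, site_qual = NULL,
                        subjects = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(sm))
    stop("genotype matrix has ", ncol(calls), " sites but site map has ",
         nrow(sm))
  if (any(!is.na(calls) & !(calls %in% 0:2)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(calls)))
  if (is.null(gq)) gq <- matrix(99, nrow(calls), ncol(calls))
  if (is.null(site_qual)) site_qual <- rep(99, ncol(calls))
  gq <- as.matrix(gq)
  if (!all(dim(gq) == dim(calls))) stop("GQ matrix shape mismatch")
  if (length(site_qual) != ncol(calls)) stop("site_qual length mismatch")
  if (any(gq < 0, na.rm = TRUE) || any(site_qual < 0, na.rm = TRUE))
    stop("phred-scaled qualities must be >= 0")
  rownames(calls) <- subjects
  structure(
    list(calls = calls, gq = gq, site_qual = as.numeric(site_qual),
         site_map = sm, subjects = as.character(subjects)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d subjects x %d sites (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

subset_geno <- function(gm, sites = NULL, subjects = NULL) {
  calls <- gm$calls; gq <- gm$gq; sq <- gm$site_qual
  sm <- gm$site_map; subj <- gm$subjects
  if (!is.null(subjects)) {
    calls <- calls[subjects, , drop = FALSE]
    gq <- gq[subjects, , drop = FALSE]
    subj <- subj[subjects]
  }
  if (!is.null(sites)) {
    calls <- calls[, sites, drop = FALSE]
    gq <- gq[, sites, drop = FALSE]
    sq <- sq[sites]
    sm <- sm[sites, , drop = FALSE]
    class(sm) <- c("site_map", "data.frame")
  }
  geno_matrix(calls, sm, gq, sq, subj)
}

site_key <- function(sm) paste(sm$pos, sm$ref, sm$alt, sep = ":")
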