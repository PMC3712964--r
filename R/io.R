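## Format readers and writers: VCF 4.2 (via vcfR for parsing), IMPUTE2
## hap/legend/sample, 3-column genetic map, and tab-separated reports with
## provenance comment headers.

pkg_version <- function() {
  as.character(utils::packageVersion("panelaug"))
}

provenance_lines <- function(seed = NA, config_hash = NA, prefix = "##") {
  sprintf("%spanelaug=%s; seed=%s; config=%s", prefix, pkg_version(),
          as.character(seed), as.character(config_hash))
}

gt_string <- function(calls, phased) {
  sep <- if (phased) "|" else "/"
  out <- matrix(".", nrow(calls), ncol(calls))
  out[calls == 0L] <- paste0("0", sep, "0")
  out[calls == 1L] <- paste0("0", sep, "1")
  out[calls == 2L] <- paste0("1", sep, "1")
  out[is.na(calls)] <- paste0(".", sep, ".")
  out
}

info_string <- function(sm) {
  sprintf("CM=%.17g;EX=%d;ARR=%d;MM=%d", sm$cm,
          as.integer(sm$is_exomic), as.integer(sm$is_array),
          as.integer(sm$is_multimap))
}

#' Write a genotype matrix or haplotype panel as VCF 4.2
#'
#' Genotype matrices are written with unphased GT plus GQ (and DS when a
#' dosage matrix is supplied) and the per-site QUAL; haplotype panels are
#' written with phased GT. Genetic position and site-class flags travel in
#' INFO (`CM`, `EX`, `ARR`, `MM`) so that the file round-trips losslessly.
#'
#' @param x a [geno_matrix] or [hap_panel].
#' @param path output path (plain text).
#' @param dosage optional numeric matrix of dosages (subjects x sites),
#'   written as a DS FORMAT field.
#' @param seed,config_hash provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, dosage = NULL, seed = NA, config_hash = NA) {
  sm <- x$site_map
  header <- c(
    "##fileformat=VCFv4.2",
    provenance_lines(seed, config_hash),
    "##contig=<ID=chr1>",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position (cM)\">",
    "##INFO=<ID=EX,Number=1,Type=Integer,Description=\"Exomic site\">",
    "##INFO=<ID=ARR,Number=1,Type=Integer,Description=\"Array site\">",
    "##INFO=<ID=MM,Number=1,Type=Integer,Description=\"Multi-mapping\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (inherits(x, "geno_matrix")) {
    header <- c(header,
      "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">")
    fmt <- "GT:GQ"
    gt <- gt_string(x$calls, phased = FALSE)
    body <- matrix(paste(gt, formatC(x$gq, format = "fg"), sep = ":"),
                   nrow(x$calls), ncol(x$calls))
    if (!is.null(dosage)) {
      header <- c(header,
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">")
      fmt <- "GT:GQ:DS"
      body <- matrix(paste(body, sprintf("%.17g", dosage), sep = ":"),
                     nrow(body), ncol(body))
    }
    samples <- x$subjects
    qual <- formatC(x$site_qual, format = "fg")
  } else if (inherits(x, "hap_panel")) {
    fmt <- "GT"
    H <- n_haps(x)
    if (H %% 2 != 0) stop("panel with odd haplotype count cannot be ",
                          "written as diploid VCF")
    odd <- seq(1, H, by = 2)
    a1 <- x$alleles[odd, , drop = FALSE]
    a2 <- x$alleles[odd + 1, , drop = FALSE]
    chr <- function(a) ifelse(is.na(a), ".", as.character(a))
    body <- matrix(paste0(chr(a1), "|", chr(a2)), length(odd), ncol(a1))
    samples <- x$subject_ids[odd]
    if (anyNA(samples)) samples <- paste0("H", odd, "_", odd + 1)
    qual <- rep(".", nrow(sm))
  } else stop("unsupported object for VCF writing")

  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples)
  rows <- vapply(seq_len(nrow(sm)), function(j) {
    paste(c(sm$chrom[j], sm$pos[j], sm$id[j], sm$ref[j], sm$alt[j],
            qual[j], "PASS", info_string(sm[j, , drop = FALSE]), fmt,
            body[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

info_field <- function(info, tag) {
  m <- regmatches(info, regexpr(paste0(tag, "=[^;]+"), info))
  as.numeric(sub(paste0(tag, "="), "", m))
}

site_map_from_vcf <- function(fix) {
  info <- fix[, "INFO"]
  cm <- info_field(info, "CM")
  if (length(cm) != nrow(fix)) cm <- as.numeric(fix[, "POS"]) * 1e-6
  flag <- function(tag) {
    v <- info_field(info, tag)
    if (length(v) != nrow(fix)) rep(FALSE, nrow(fix)) else v == 1
  }
  site_map(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
           id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
           cm = cm, is_exomic = flag("EX"), is_array = flag("ARR"),
           is_multimap = flag("MM"))
}

read_vcf_raw <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(vcf@gt) == 0) stop("malformed or empty VCF")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  list(vcf = vcf, fix = fix, n_multiallelic = sum(multi))
}

#' Read a VCF into a diploid genotype matrix
#'
#' Multi-allelic records are skipped with a warning (the skip count is
#' attached as attribute `n_multiallelic_skipped`). GT is summed to 0/1/2;
#' GQ and QUAL are recovered where present; a DS field, if present, is
#' attached as attribute `dosage`.
#'
#' @param path a VCF 4.2 file.
#' @return A [geno_matrix].
#' @export
read_vcf_genotypes <- function(path) {
  raw <- read_vcf_raw(path)
  sm <- site_map_from_vcf(raw$fix)
  gt <- vcfR::extract.gt(raw$vcf, element = "GT")
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt))
  for (al in list(c("0/0", "0|0", 0L), c("0/1", "0|1", 1L),
                  c("1/0", "1|0", 1L), c("1/1", "1|1", 2L))) {
    calls[t(gt) == al[[1]]] <- as.integer(al[[3]])
    calls[t(gt) == al[[2]]] <- as.integer(al[[3]])
  }
  gq <- tryCatch({
    g <- vcfR::extract.gt(raw$vcf, element = "GQ", as.numeric = TRUE)
    t(g)
  }, error = function(e) NULL)
  qual <- suppressWarnings(as.numeric(raw$fix[, "QUAL"]))
  if (all(is.na(qual))) qual <- rep(99, nrow(sm))
  gm <- geno_matrix(calls, sm, gq = gq, site_qual = qual,
                    subjects = colnames(gt))
  ds <- tryCatch(vcfR::extract.gt(raw$vcf, element = "DS",
                                  as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(ds) && !all(is.na(ds))) attr(gm, "dosage") <- t(ds)
  attr(gm, "n_multiallelic_skipped") <- raw$n_multiallelic
  gm
}

#' Read a VCF of phased genotypes as a haplotype panel
#'
#' Every non-missing GT must be phased (`|` separator); unphased records
#' are an error. Each sample contributes two haplotypes paired under the
#' sample id.
#'
#' @param path a VCF 4.2 file with phased GT.
#' @return A [hap_panel].
#' @export
read_vcf_panel <- function(path) {
  raw <- read_vcf_raw(path)
  sm <- site_map_from_vcf(raw$fix)
  gt <- t(vcfR::extract.gt(raw$vcf, element = "GT"))  # samples x sites
  nonmiss <- !is.na(gt) & gt != ".|." & gt != "./."
  if (any(grepl("/", gt[nonmiss], fixed = TRUE)))
    stop("unphased genotypes cannot be read as a haplotype panel")
  samples <- rownames(gt)
  n <- length(samples)
  a <- matrix(NA_integer_, 2 * n, nrow(sm))
  parse_hap <- function(x, which)
    suppressWarnings(as.integer(vapply(strsplit(x, "|", fixed = TRUE),
                                       `[`, character(1), which)))
  for (i in seq_len(n)) {
    a[2 * i - 1, ] <- parse_hap(gt[i, ], 1L)
    a[2 * i, ] <- parse_hap(gt[i, ], 2L)
  }
  hap_panel(a, sm,
            hap_ids = paste0(rep(samples, each = 2), c("_h1", "_h2")),
            subject_ids = rep(samples, each = 2))
}

#' Write a haplotype panel in IMPUTE2 hap/legend/sample format
#'
#' `.hap` holds one row per site, one 0/1 column per haplotype (`?` for
#' missing); `.legend` holds `id position a0 a1`; `.sample` lists the
#' subject pairing.
#'
#' @param panel a [hap_panel].
#' @param prefix path prefix; the three files get `.hap`, `.legend`,
#'   `.sample` appended.
#' @return `prefix`, invisibly.
#' @export
write_impute2_panel <- function(panel, prefix) {
  a <- t(panel$alleles)  # sites x haps
  a[is.na(a)] <- "?"
  writeLines(apply(a, 1, paste, collapse = " "), paste0(prefix, ".hap"))
  leg <- data.frame(id = panel$site_map$id, position = panel$site_map$pos,
                    a0 = panel$site_map$ref, a1 = panel$site_map$alt)
  utils::write.table(leg, paste0(prefix, ".legend"), quote = FALSE,
                     row.names = FALSE)
  subj <- panel$subject_ids
  subj[is.na(subj)] <- panel$hap_ids[is.na(subj)]
  samp <- data.frame(ID_1 = subj[seq(1, length(subj), by = 2)],
                     ID_2 = panel$hap_ids[seq(1, length(subj), by = 2)],
                     missing = 0)
  utils::write.table(samp, paste0(prefix, ".sample"), quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' Read an IMPUTE2 hap/legend/sample trio as a haplotype panel
#'
#' @param prefix path prefix as in [write_impute2_panel()].
#' @param sm optional [site_map] carrying genetic positions; when absent a
#'   uniform 1 cM/Mb map is assumed.
#' @return A [hap_panel].
#' @export
read_impute2_panel <- function(prefix, sm = NULL) {
  leg <- utils::read.table(paste0(prefix, ".legend"), header = TRUE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(leg$position))
    stop("duplicated position in ", prefix, ".legend")
  hap_rows <- readLines(paste0(prefix, ".hap"))
  if (length(hap_rows) != nrow(leg))
    stop("row count mismatch between ", prefix, ".hap and ", prefix,
         ".legend")
  toks <- strsplit(trimws(hap_rows), "\\s+")
  H <- length(toks[[1]])
  if (any(lengths(toks) != H))
    stop("ragged haplotype columns in ", prefix, ".hap")
  a <- matrix(NA_integer_, H, nrow(leg))
  for (j in seq_along(toks))
    a[, j] <- suppressWarnings(as.integer(toks[[j]]))
  samp <- utils::read.table(paste0(prefix, ".sample"), header = TRUE,
                            stringsAsFactors = FALSE)
  if (2 * nrow(samp) != H)
    stop("sample count in ", prefix, ".sample does not match ", prefix,
         ".hap columns")
  if (is.null(sm))
    sm <- site_map(chrom = "chr1", pos = leg$position, id = leg$id,
                   ref = leg$a0, alt = leg$a1, cm = leg$position * 1e-6)
  subj <- rep(samp$ID_1, each = 2)
  hap_panel(a, sm, hap_ids = paste0(subj, c("_h1", "_h2")),
            subject_ids = subj)
}

#' Write the genetic map as 3-column text
#'
#' Columns: position (bp), local recombination rate (cM/Mb), cumulative
#' genetic position (cM).
#'
#' @param sm a [site_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(sm, path) {
  rate <- c(diff(sm$cm) / diff(sm$pos) * 1e6, 0)
  writeLines(c(
    "position COMBINED_rate(cM/Mb) Genetic_Map(cM)",
    sprintf("%d %.17g %.17g", sm$pos, rate, sm$cm)
  ), path)
  invisible(path)
}

#' Read a 3-column genetic map
#'
#' @param path map file written by [write_genetic_map()] (or in the same
#'   dialect).
#' @return A `data.frame` with columns `pos`, `rate_cm_mb`, `cm`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  m <- utils::read.table(path, header = FALSE, skip = 1,
                         col.names = c("pos", "rate_cm_mb", "cm"))
  m
}

#' Interpolate genetic positions from a map
#'
#' @param map a `data.frame` from [read_genetic_map()].
#' @param pos base-pair positions to interpolate at.
#' @return Genetic positions in cM.
#' @export
map_cm_at <- function(map, pos) {
  stats::approx(map$pos, map$cm, xout = pos, rule = 2)$y
}

#' Write a data frame as a provenance-stamped TSV report
#'
#' @param df the table.
#' @param path output path.
#' @param seed,config_hash provenance recorded in the leading comment.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed, config_hash, prefix = "# "), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_report_tsv()]
#' @param path the report path.
#' @return A `data.frame`.
#' @export
read_report_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
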