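#' Remove peaks near transcription start sites
#'
#' Promoter-proximal peaks are excluded before any prevalence analysis, so
#' that the site universe is restricted to putative distal regulatory
#' elements. A peak is removed when it shares at least one base pair with the
#' window of `window_bp` base pairs on either side of a TSS; the window is
#' half-open, so the base exactly `window_bp` downstream of the TSS is
#' outside it.
#'
#' @param peaks A `GRanges` of peaks (typically one patient's peak set).
#' @param tss A `GRanges` of TSS positions; only the start coordinate of each
#'   range is used as the TSS base.
#' @param window_bp Half-width of the exclusion window in base pairs
#'   (default 1000).
#' @return A `GRanges` with the promoter-proximal peaks removed.
#' @export
exclude_tss <- function(peaks, tss, window_bp = 1000L) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(tss, "GRanges"))
  if (length(window_bp) != 1L || is.na(window_bp) || window_bp < 0)
    stop("window_bp must be a single nonnegative number")
  if (length(tss) == 0L || length(peaks) == 0L || window_bp == 0)
    return(peaks)
  zone <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(tss) - as.integer(window_bp)),
      end   = GenomicRanges::start(tss) + as.integer(window_bp) - 1L
    )
  )
  keep <- !IRanges::overlapsAny(peaks, zone, ignore.strand = TRUE)
  peaks[keep]
}

#' Build the cross-cohort site universe
#'
#' Pools all patients' peaks and merges them by single linkage: two peaks
#' belong to the same universe site when they share at least one base pair,
#' possibly through a chain of intermediate peaks. Each patient contributes
#' at most one occurrence per site (prevalence is per patient, not per
#' peak); when several of a patient's peaks fall in one site the maximum
#' score is taken. Occurrence-matrix entries are `log(score + 1)` for
#' present sites and exactly 0 for absent ones, so absence and presence are
#' separable in downstream regression designs.
#'
#' @param peak_sets Named list of `GRanges`, one per patient, each with a
#'   numeric `score` metadata column. Names are patient ids.
#' @return An object of class `site_universe` with elements
#'   \describe{
#'     \item{sites}{`GRanges` with metadata columns `site_id`, `prevalence`,
#'       `rank`, `bin` (`rank`/`bin` are `NA` until [rank_and_bin()]).}
#'     \item{n_patients}{Number of patients.}
#'     \item{occurrence}{patients x sites matrix of `log(score + 1)`,
#'       0 where absent.}
#'     \item{presence}{Companion logical matrix.}
#'   }
#' @seealso [rank_and_bin()], [prevalence_consensus()]
#' @export
build_universe <- function(peak_sets) {
  if (!is.list(peak_sets) || length(peak_sets) == 0L)
    stop("peak_sets must be a non-empty named list of GRanges")
  if (is.null(names(peak_sets)) || anyDuplicated(names(peak_sets)) ||
      any(!nzchar(names(peak_sets))))
    stop("peak_sets must have unique non-empty patient-id names")
  ok <- vapply(peak_sets, methods::is, logical(1), class2 = "GRanges")
  if (!all(ok)) stop("every element of peak_sets must be a GRanges")
  for (nm in names(peak_sets)) {
    gr <- peak_sets[[nm]]
    if (length(gr) > 0L &&
        (is.null(gr$score) || !is.numeric(gr$score) || anyNA(gr$score) ||
         any(gr$score < 0)))
      stop("peak set '", nm, "' needs a nonnegative numeric 'score' column")
  }
  patients <- names(peak_sets)
  n_pat <- length(patients)
  all_peaks <- suppressWarnings(do.call(c, unname(peak_sets)))
  if (length(all_peaks) == 0L) stop("no peaks in any patient peak set")
  pat_idx <- rep(seq_len(n_pat), lengths(peak_sets))

  # min.gapwidth = 0: merge only true overlaps, never book-ended intervals
  sites <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
  # deterministic genomic order: chromosome lexicographic, then start
  GenomeInfoDb::seqlevels(sites) <-
    sort(GenomeInfoDb::seqlevels(sites))
  sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)
  n_sites <- length(sites)

  hits <- GenomicRanges::findOverlaps(sites, all_peaks, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  pi <- pat_idx[S4Vectors::subjectHits(hits)]
  sc <- all_peaks$score[S4Vectors::subjectHits(hits)]
  # per (site, patient): presence once, score = max over that patient's peaks
  occ <- matrix(0, nrow = n_pat, ncol = n_sites,
                dimnames = list(patients, NULL))
  pres <- matrix(FALSE, nrow = n_pat, ncol = n_sites,
                 dimnames = list(patients, NULL))
  flat <- (si - 1L) * n_pat + pi
  mx <- tapply(sc, flat, max)
  cells <- as.integer(names(mx))
  pres[cells] <- TRUE
  occ[cells] <- log1p(as.numeric(mx))

  prevalence <- colSums(pres)
  site_id <- sprintf("site_%05d", seq_len(n_sites))
  S4Vectors::mcols(sites)$site_id <- site_id
  S4Vectors::mcols(sites)$prevalence <- as.integer(prevalence)
  S4Vectors::mcols(sites)$rank <- NA_integer_
  S4Vectors::mcols(sites)$bin <- NA_character_
  colnames(occ) <- site_id
  colnames(pres) <- site_id

  structure(
    list(sites = sites, n_patients = n_pat, sh_fraction = NA_real_,
         sh_min_patients = NA_integer_, occurrence = occ, presence = pres),
    class = "site_universe"
  )
}

#' @export
print.site_universe <- function(x, ...) {
  cat("site_universe:", length(x$sites), "sites across", x$n_patients,
      "patients\n")
  if (!is.na(x$sh_min_patients)) {
    tab <- table(factor(x$sites$bin, levels = c("SH", "PS", "UN")))
    cat("  bins (SH >=", x$sh_min_patients, "patients): SH", tab[["SH"]],
        "| PS", tab[["PS"]], "| UN", tab[["UN"]], "\n")
  } else {
    cat("  not yet ranked/binned; see rank_and_bin()\n")
  }
  invisible(x)
}

#' Rank sites by prevalence and bin into shared / partially shared / unique
#'
#' Sites are sorted by prevalence (descending), with ties broken by
#' chromosome (lexicographic) then start coordinate. Bins: unique (UN) if
#' the site occurs in exactly one patient; shared (SH) if its prevalence is
#' at least `ceiling(sh_fraction * n_patients)`; partially shared (PS)
#' otherwise. With the default `sh_fraction = 0.68` an 88-patient cohort
#' has an SH threshold of 60 patients. Unique membership never depends on
#' `sh_fraction`.
#'
#' @param universe A `site_universe` from [build_universe()].
#' @param sh_fraction Minimum fraction of the cohort defining a shared
#'   site, in (0, 1].
#' @return The universe with sites reordered by rank and with `rank` and
#'   `bin` metadata filled in; occurrence/presence columns are reordered to
#'   match.
#' @export
rank_and_bin <- function(universe, sh_fraction = 0.68) {
  stopifnot(inherits(universe, "site_universe"))
  if (length(sh_fraction) != 1L || is.na(sh_fraction) ||
      sh_fraction <= 0 || sh_fraction > 1)
    stop("sh_fraction must be a single value in (0, 1]")
  sites <- universe$sites
  ord <- order(-sites$prevalence,
               as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites))
  sites <- sites[ord]
  sh_min <- as.integer(ceiling(sh_fraction * universe$n_patients))
  prev <- sites$prevalence
  bin <- ifelse(prev == 1L, "UN", ifelse(prev >= sh_min, "SH", "PS"))
  S4Vectors::mcols(sites)$rank <- seq_along(sites)
  S4Vectors::mcols(sites)$bin <- bin
  universe$sites <- sites
  universe$sh_fraction <- sh_fraction
  universe$sh_min_patients <- sh_min
  universe$occurrence <- universe$occurrence[, sites$site_id, drop = FALSE]
  universe$presence <- universe$presence[, sites$site_id, drop = FALSE]
  universe
}

#' Sequential per-prevalence consensus regions
#'
#' Returns the regions occupied at exactly the given prevalence level,
#' minus any region already emitted at a higher level. Consensus sets are
#' therefore pairwise disjoint across levels and their union covers the
#' universe. On a universe of merged (disjoint) sites the subtraction is a
#' no-op, but it matters when site lists from other sources overlap.
#'
#' @param universe A `site_universe`.
#' @param level Prevalence level, between 1 and the number of patients.
#' @return A `GRanges` of consensus regions (may be empty).
#' @export
prevalence_consensus <- function(universe, level) {
  stopifnot(inherits(universe, "site_universe"))
  if (length(level) != 1L || is.na(level) || level < 1 ||
      level > universe$n_patients)
    stop("level must be between 1 and n_patients")
  sites <- universe$sites
  at <- sites[sites$prevalence == level]
  if (length(at) == 0L) return(GenomicRanges::granges(at))
  higher <- sites[sites$prevalence > level]
  if (length(higher) == 0L)
    return(GenomicRanges::reduce(GenomicRanges::granges(at),
                                 min.gapwidth = 0L))
  GenomicRanges::setdiff(GenomicRanges::granges(at),
                         GenomicRanges::granges(higher),
                         ignore.strand = TRUE)
}

#' Normalize prevalence to the fraction of the cohort
#'
#' @param universe A `site_universe`.
#' @return Numeric vector, one value per site in current site order:
#'   `prevalence / n_patients`, in (0, 1].
#' @export
normalize_prevalence <- function(universe) {
  stopifnot(inherits(universe, "site_universe"))
  if (universe$n_patients <= 0) stop("n_patients must be positive")
  stats::setNames(universe$sites$prevalence / universe$n_patients,
                  universe$sites$site_id)
}

#' Write the universe site table as TSV
#'
#' Columns: chrom, start (0-based), end, site_id, prevalence, rank, bin.
#'
#' @param universe A `site_universe`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_universe_tsv <- function(universe, path) {
  stopifnot(inherits(universe, "site_universe"))
  s <- universe$sites
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(s)),
    start = GenomicRanges::start(s) - 1L,
    end = GenomicRanges::end(s),
    site_id = s$site_id,
    prevalence = s$prevalence,
    rank = s$rank,
    bin = s$bin,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
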