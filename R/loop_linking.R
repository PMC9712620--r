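#' Construct a set of chromatin loops
#'
#' A loop is an unordered pair of genomic anchors in 3D contact (e.g.
#' H3K27ac HiChIP anchors).
#'
#' @param anchor1,anchor2 Parallel `GRanges` of equal length.
#' @param score Optional numeric loop scores.
#' @param name Optional character names (e.g. the BEDPE name column).
#' @return An object of class `loop_set`.
#' @export
loop_set <- function(anchor1, anchor2, score = NULL, name = NULL) {
  stopifnot(methods::is(anchor1, "GRanges"), methods::is(anchor2, "GRanges"),
            length(anchor1) == length(anchor2))
  if (!is.null(score)) stopifnot(length(score) == length(anchor1))
  if (!is.null(name)) stopifnot(length(name) == length(anchor1))
  structure(list(anchor1 = anchor1, anchor2 = anchor2,
                 score = score, name = name),
            class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat("loop_set:", length(x$anchor1), "anchor pairs\n")
  invisible(x)
}

#' @export
length.loop_set <- function(x) length(x$anchor1)

#' Keep promoter-enhancer loops and assign them to genes
#'
#' A loop is retained when exactly one of its anchors overlaps at least
#' one gene promoter; that anchor fixes the gene assignment(s) and the
#' other anchor is the enhancer anchor. A promoter anchor covering two
#' genes (bidirectional promoter) yields one record per gene.
#' Promoter-promoter loops are dropped by default.
#'
#' @param loops A [loop_set()].
#' @param promoters `GRanges` of promoters with a `gene_id` metadata
#'   column.
#' @param drop_promoter_promoter Drop loops whose both anchors touch
#'   promoters (default TRUE). When FALSE, such loops are assigned from
#'   each promoter anchor in turn, with the opposite anchor as enhancer.
#' @return A `gene_loops` object: list with `gene_id` (character) and
#'   `enhancer` (`GRanges`), parallel vectors with one entry per
#'   (gene, loop) assignment.
#' @export
filter_promoter_loops <- function(loops, promoters,
                                  drop_promoter_promoter = TRUE) {
  stopifnot(inherits(loops, "loop_set"), methods::is(promoters, "GRanges"))
  if (length(promoters) == 0L) stop("promoter map is empty")
  if (is.null(promoters$gene_id))
    stop("promoters need a gene_id metadata column")
  h1 <- GenomicRanges::findOverlaps(loops$anchor1, promoters,
                                    ignore.strand = TRUE)
  h2 <- GenomicRanges::findOverlaps(loops$anchor2, promoters,
                                    ignore.strand = TRUE)
  on1 <- seq_along(loops$anchor1) %in% S4Vectors::queryHits(h1)
  on2 <- seq_along(loops$anchor2) %in% S4Vectors::queryHits(h2)
  gene_id <- character(0)
  enh_idx <- integer(0)        # loop index
  enh_from2 <- logical(0)      # TRUE: enhancer anchor is anchor2
  add <- function(hits, loop_on_other, from2) {
    li <- S4Vectors::queryHits(hits)
    keep <- if (drop_promoter_promoter) !loop_on_other[li] else
      rep(TRUE, length(li))
    gene_id <<- c(gene_id, promoters$gene_id[S4Vectors::subjectHits(hits)[keep]])
    enh_idx <<- c(enh_idx, li[keep])
    enh_from2 <<- c(enh_from2, rep(from2, sum(keep)))
  }
  add(h1, on2, from2 = TRUE)   # promoter on anchor1 -> enhancer = anchor2
  add(h2, on1, from2 = FALSE)
  enh <- c(GenomicRanges::granges(loops$anchor2)[enh_idx[enh_from2]],
           GenomicRanges::granges(loops$anchor1)[enh_idx[!enh_from2]])
  gene_id <- c(gene_id[enh_from2], gene_id[!enh_from2])
  structure(list(gene_id = gene_id, enhancer = enh),
            class = "gene_loops")
}

#' Build per-gene enhancer landscapes
#'
#' A gene's landscape is the set of universe sites overlapping any of its
#' enhancer anchors, deduplicated.
#'
#' @param gene_loops A `gene_loops` object from [filter_promoter_loops()].
#' @param universe A `site_universe`.
#' @return Named list (by gene id) of data frames with columns `site_id`
#'   and `prevalence`. Genes with loops but no overlapping universe site
#'   get a zero-row data frame.
#' @export
build_gene_landscapes <- function(gene_loops, universe) {
  stopifnot(inherits(gene_loops, "gene_loops"),
            inherits(universe, "site_universe"))
  genes <- unique(gene_loops$gene_id)
  hits <- GenomicRanges::findOverlaps(gene_loops$enhancer, universe$sites,
                                      ignore.strand = TRUE)
  li <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- lapply(stats::setNames(nm = genes), function(g) {
    idx <- unique(si[gene_loops$gene_id[li] == g])
    idx <- idx[order(universe$sites$site_id[idx])]
    data.frame(site_id = universe$sites$site_id[idx],
               prevalence = universe$sites$prevalence[idx],
               stringsAsFactors = FALSE)
  })
  out
}

#' Partition copy-number events into gene-exclusive and enhancer-exclusive
#'
#' For a given gene, a non-neutral segment is `gene_exclusive` when it
#' overlaps the gene's coding sequence but none of its linked enhancer
#' sites, `enhancer_exclusive` when it overlaps at least one linked site
#' but not the CDS, and `mixed` otherwise (excluded from both exclusive
#' classes). Exclusivity is evaluated per gene, relative to that gene's
#' own CDS and landscape. When an expression matrix is supplied, each
#' event is annotated with the patient's expression log2 fold change over
#' the median of copy-number-neutral patients for that gene (patients with
#' no non-neutral segment touching the gene's CDS or landscape;
#' expression is assumed to be on a log2 scale).
#'
#' @param segments Data frame of segments with columns `patient_id, chrom,
#'   start, end, call` (`start` 0-based, half-open; `call` one of gain,
#'   loss, neutral).
#' @param gene_cds Named list (by gene id) of `GRanges` coding-sequence
#'   intervals.
#' @param landscapes Landscapes from [build_gene_landscapes()].
#' @param universe The `site_universe` the landscapes refer to.
#' @param expression Optional genes x patients numeric matrix.
#' @return Data frame with one row per (gene, non-neutral overlapping
#'   segment): `gene_id, patient_id, chrom, start, end, call, class,
#'   log2fc`.
#' @export
partition_cna_exclusive <- function(segments, gene_cds, landscapes,
                                    universe, expression = NULL) {
  stopifnot(is.data.frame(segments), inherits(universe, "site_universe"))
  need <- c("patient_id", "chrom", "start", "end", "call")
  if (!all(need %in% names(segments)))
    stop("segments need columns ", paste(need, collapse = ", "))
  bad <- !segments$call %in% c("gain", "loss", "neutral")
  if (any(bad)) stop("unknown CNA call(s): ",
                     paste(unique(segments$call[bad]), collapse = ", "))
  seg <- segments[segments$call != "neutral", , drop = FALSE]
  seg_gr <- GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end))
  site_map <- stats::setNames(seq_along(universe$sites),
                              universe$sites$site_id)
  rows <- list()
  for (g in names(landscapes)) {
    cds <- gene_cds[[g]]
    if (is.null(cds)) next
    sites <- universe$sites[site_map[landscapes[[g]]$site_id]]
    hit_cds <- IRanges::overlapsAny(seg_gr, cds, ignore.strand = TRUE)
    hit_enh <- if (length(sites) > 0)
      IRanges::overlapsAny(seg_gr, sites, ignore.strand = TRUE)
    else rep(FALSE, length(seg_gr))
    rel <- which(hit_cds | hit_enh)
    if (length(rel) == 0L) next
    klass <- ifelse(hit_cds[rel] & hit_enh[rel], "mixed",
                    ifelse(hit_cds[rel], "gene_exclusive",
                           "enhancer_exclusive"))
    l2fc <- rep(NA_real_, length(rel))
    if (!is.null(expression) && g %in% rownames(expression)) {
      affected <- unique(seg$patient_id[rel])
      neutral <- setdiff(colnames(expression), affected)
      if (length(neutral) > 0) {
        ref <- stats::median(expression[g, neutral])
        ok <- seg$patient_id[rel] %in% colnames(expression)
        l2fc[ok] <- expression[g, seg$patient_id[rel][ok]] - ref
      }
    }
    rows[[g]] <- data.frame(
      gene_id = g, patient_id = seg$patient_id[rel],
      chrom = seg$chrom[rel], start = seg$start[rel], end = seg$end[rel],
      call = seg$call[rel], class = klass, log2fc = unname(l2fc),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), patient_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), call = character(0),
                      class = character(0), log2fc = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter genes by CRISPR dependency score
#'
#' Keeps genes whose dependency effect score is strictly below the
#' threshold (more negative = more essential); the default -0.5 is the
#' conventional cutoff for calling a gene dependent.
#'
#' @param scores Named numeric vector of per-gene dependency scores.
#' @param threshold Strict upper bound (default -0.5); a score exactly at
#'   the threshold is excluded.
#' @return Character vector of dependent gene names.
#' @export
dependency_filter <- function(scores, threshold = -0.5) {
  stopifnot(is.numeric(scores))
  if (length(scores) == 0L) return(character(0))
  if (is.null(names(scores))) stop("scores must be named by gene")
  names(scores)[!is.na(scores) & scores < threshold]
}
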