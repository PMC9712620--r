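# ---- validated readers for the plain-text interchange formats ----------
# All genomic text formats are BED-convention 0-based half-open on disk;
# in memory everything is 1-based closed GRanges.

.read_lines_table <- function(path, min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "")
  if (length(nf) == 0 || all(is.na(nf)))
    return(NULL)
  bad <- which(nf < min_cols)
  if (length(bad) > 0)
    stop(what, " parse error in ", path, ": line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " have fewer than ", min_cols, " tab-separated fields")
  utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                    header = FALSE, stringsAsFactors = FALSE)
}

.check_coords <- function(start, end, path, offset = 0L) {
  if (!is.numeric(start) || !is.numeric(end) || anyNA(start) || anyNA(end))
    stop("non-numeric coordinates in ", path)
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0)
    stop("invalid interval(s) (start >= end or start < 0) in ", path,
         " at line(s) ", paste(utils::head(bad + offset, 5), collapse = ", "))
}

#' Read genomic intervals from BED or ENCODE narrowPeak
#'
#' `format = "bed"` accepts BED3/BED6 (name and score kept when present).
#' `format = "narrowpeak"` requires the 10-column ENCODE layout; the
#' `score_col` argument selects column 7 (`signalValue`, default) or
#' column 5 (`score`) as the peak score. Malformed lines are rejected
#' with their line numbers.
#'
#' @param path File path.
#' @param format `"bed"` or `"narrowpeak"`.
#' @param score_col For narrowPeak: `"signalValue"` or `"score"`.
#' @return A `GRanges`; an empty file yields an empty `GRanges`.
#' @export
read_intervals <- function(path, format = c("bed", "narrowpeak"),
                           score_col = c("signalValue", "score")) {
  format <- match.arg(format)
  score_col <- match.arg(score_col)
  min_cols <- if (format == "narrowpeak") 10L else 3L
  df <- .read_lines_table(path, min_cols, format)
  if (is.null(df))
    return(GenomicRanges::GRanges())
  .check_coords(df[[2]], df[[3]], path)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  if (format == "narrowpeak") {
    sc <- if (score_col == "signalValue") df[[7]] else df[[5]]
    if (!is.numeric(sc)) stop("non-numeric score column in ", path)
    S4Vectors::mcols(gr)$name <- as.character(df[[4]])
    S4Vectors::mcols(gr)$score <- as.numeric(sc)
  } else {
    if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- as.character(df[[4]])
    if (ncol(df) >= 5 && is.numeric(df[[5]]))
      S4Vectors::mcols(gr)$score <- as.numeric(df[[5]])
  }
  gr
}

#' Read loops from BEDPE
#'
#' Requires at least the six coordinate columns; column 7 (name) and 8
#' (score) are kept when present.
#'
#' @param path File path.
#' @return A [loop_set()].
#' @export
read_bedpe <- function(path) {
  df <- .read_lines_table(path, 6L, "bedpe")
  if (is.null(df))
    return(loop_set(GenomicRanges::GRanges(), GenomicRanges::GRanges()))
  .check_coords(df[[2]], df[[3]], path)
  .check_coords(df[[5]], df[[6]], path)
  a1 <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  a2 <- GenomicRanges::GRanges(df[[4]],
                               IRanges::IRanges(df[[5]] + 1L, df[[6]]))
  nm <- if (ncol(df) >= 7) as.character(df[[7]]) else NULL
  sc <- if (ncol(df) >= 8 && is.numeric(df[[8]])) as.numeric(df[[8]])
  else NULL
  loop_set(a1, a2, score = sc, name = nm)
}

#' Read point mutations
#'
#' Accepts BED3 (0-based half-open) or a two-column chrom/position list
#' (1-based positions), converted to width-1 intervals.
#'
#' @param path File path.
#' @return A width-1 `GRanges`.
#' @export
read_mutations <- function(path) {
  df <- .read_lines_table(path, 2L, "mutations")
  if (is.null(df)) return(GenomicRanges::GRanges())
  if (ncol(df) >= 3 && is.numeric(df[[3]])) {
    .check_coords(df[[2]], df[[3]], path)
    return(GenomicRanges::GRanges(df[[1]],
                                  IRanges::IRanges(df[[2]] + 1L, df[[3]])))
  }
  if (!is.numeric(df[[2]]) || any(df[[2]] < 1))
    stop("invalid positions in ", path)
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]], width = 1L))
}

#' Read a genes x patients expression matrix
#'
#' TSV with a header line; the first column holds gene ids, remaining
#' columns are patients. Duplicate gene ids and non-numeric cells are
#' rejected with their location.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and patient colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs gene ids plus >= 1 ",
                         "patient column: ", path)
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0)
    stop("duplicate gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric expression column(s) in ", path, ": ",
         paste(names(df)[-1][bad], collapse = ", "))
  }
  rownames(m) <- genes
  m
}

#' Read copy-number segments
#'
#' TSV with header `chrom start end call` (start 0-based) and an optional
#' `log2fc` column; an optional `patient_id` column allows a single
#' multi-patient file.
#'
#' @param path File path.
#' @param patient_id Patient id to attach when the file has no
#'   `patient_id` column.
#' @return Data frame `patient_id, chrom, start, end, call[, log2fc]`.
#' @export
read_cna <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "call")
  if (!all(need %in% names(df)))
    stop("CNA file ", path, " needs columns ", paste(need, collapse = ", "))
  if (nrow(df) > 0) .check_coords(df$start, df$end, path, offset = 1L)
  if (!"patient_id" %in% names(df)) {
    if (is.null(patient_id)) stop("no patient_id column in ", path,
                                  " and none supplied")
    df$patient_id <- rep(patient_id, nrow(df))
  }
  df[, c("patient_id", need, intersect("log2fc", names(df)))]
}

#' Read patient outcome labels
#'
#' TSV with header `patient_id label`.
#'
#' @param path File path.
#' @return Named character vector patient id -> label.
#' @export
read_outcome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("patient_id", "label") %in% names(df)))
    stop("outcome file needs columns patient_id, label: ", path)
  stats::setNames(as.character(df$label), as.character(df$patient_id))
}

# ---- writers ------------------------------------------------------------

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a `GRanges` as BED
#'
#' @param gr A `GRanges`; `name`/`score` metadata columns are written as
#'   BED columns 4 and 5 when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  cols <- list(chrom, start, end)
  if (!is.null(gr$name)) {
    cols <- c(cols, list(gr$name))
    if (!is.null(gr$score)) cols <- c(cols, list(.fmt_num(gr$score)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a scored `GRanges` as ENCODE narrowPeak
#'
#' The `score` metadata column goes to column 7 (signalValue); columns
#' 5, 8-10 are placeholders.
#'
#' @inheritParams write_bed
#' @export
write_narrowpeak <- function(gr, path) {
  if (length(gr) > 0 && is.null(gr$score))
    stop("GRanges needs a score metadata column")
  nm <- if (!is.null(gr$name)) gr$name else
    sprintf("peak_%d", seq_along(gr))
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr),
                 nm, 0L, ".",
                 .fmt_num(gr$score), -1L, -1L, -1L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write loops as BEDPE
#'
#' @param loops A [loop_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  stopifnot(inherits(loops, "loop_set"))
  n <- length(loops)
  nm <- if (!is.null(loops$name)) loops$name else rep(".", n)
  sc <- if (!is.null(loops$score)) .fmt_num(loops$score) else rep(".", n)
  lines <- paste(as.character(GenomicRanges::seqnames(loops$anchor1)),
                 GenomicRanges::start(loops$anchor1) - 1L,
                 GenomicRanges::end(loops$anchor1),
                 as.character(GenomicRanges::seqnames(loops$anchor2)),
                 GenomicRanges::start(loops$anchor2) - 1L,
                 GenomicRanges::end(loops$anchor2),
                 nm, sc, ".", ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a synthetic cohort as plain-text fixtures
#'
#' Layout: `peaks/<patient>.narrowPeak`, `loops.bedpe`, `expression.tsv`,
#' `mutations.bed`, `cna/<patient>.tsv`, `outcome.tsv`,
#' `annotations/<name>.bed`, and `truth.json` (ground-truth sites, causal
#' map, and generator parameters). Numeric values are written at full
#' precision so a read-back reproduces the cohort exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixtures <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (d in file.path(outdir, c("", "peaks", "cna", "annotations")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (p in names(cohort$peak_sets))
    write_narrowpeak(cohort$peak_sets[[p]],
                     file.path(outdir, "peaks", paste0(p, ".narrowPeak")))
  write_bedpe(cohort$loops, file.path(outdir, "loops.bedpe"))
  expr <- data.frame(gene_id = rownames(cohort$expression),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (p in colnames(cohort$expression))
    expr[[p]] <- .fmt_num(cohort$expression[, p])
  .write_tsv(expr, file.path(outdir, "expression.tsv"))
  write_bed(cohort$mutations, file.path(outdir, "mutations.bed"))
  for (p in names(cohort$cna))
    .write_tsv(cohort$cna[[p]], file.path(outdir, "cna",
                                          paste0(p, ".tsv")))
  .write_tsv(cohort$outcome, file.path(outdir, "outcome.tsv"))
  for (nm in names(cohort$annotations))
    write_bed(cohort$annotations[[nm]],
              file.path(outdir, "annotations", paste0(nm, ".bed")))
  truth_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cohort$truth)),
    start = GenomicRanges::start(cohort$truth) - 1L,
    end = GenomicRanges::end(cohort$truth),
    site_id = cohort$truth$site_id,
    prevalence = cohort$truth$prevalence,
    bin = cohort$truth$bin, stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(chrom_sizes = as.list(cohort$spec$chrom_sizes),
         n_patients = length(cohort$patients),
         patients = cohort$patients,
         seed = cohort$spec$seed,
         truth = truth_df,
         causal_map = cohort$causal_map),
    file.path(outdir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read back a fixture directory written by [write_fixtures()]
#'
#' @param dir Fixture directory.
#' @return List with `peak_sets`, `loops`, `expression`, `mutations`,
#'   `cna`, `outcome`, `annotations`, `truth` (a `GRanges`), and
#'   `chrom_sizes`.
#' @export
read_cohort_fixtures <- function(dir) {
  pk_files <- sort(list.files(file.path(dir, "peaks"),
                              pattern = "\\.narrowPeak$",
                              full.names = TRUE))
  if (length(pk_files) == 0) stop("no peak files under ", dir)
  peak_sets <- lapply(pk_files, read_intervals, format = "narrowpeak")
  names(peak_sets) <- sub("\\.narrowPeak$", "", basename(pk_files))
  cna_files <- sort(list.files(file.path(dir, "cna"),
                               pattern = "\\.tsv$", full.names = TRUE))
  cna <- lapply(seq_along(cna_files), function(i)
    read_cna(cna_files[i], patient_id = sub("\\.tsv$", "",
                                            basename(cna_files[i]))))
  names(cna) <- sub("\\.tsv$", "", basename(cna_files))
  ann_files <- sort(list.files(file.path(dir, "annotations"),
                               pattern = "\\.bed$", full.names = TRUE))
  annotations <- lapply(ann_files, read_intervals, format = "bed")
  names(annotations) <- sub("\\.bed$", "", basename(ann_files))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- GenomicRanges::GRanges(
    tj$truth$chrom, IRanges::IRanges(tj$truth$start + 1L, tj$truth$end),
    site_id = tj$truth$site_id, prevalence = as.integer(tj$truth$prevalence),
    bin = tj$truth$bin)
  list(peak_sets = peak_sets,
       loops = read_bedpe(file.path(dir, "loops.bedpe")),
       expression = read_matrix(file.path(dir, "expression.tsv")),
       mutations = read_mutations(file.path(dir, "mutations.bed")),
       cna = cna,
       outcome = read_outcome(file.path(dir, "outcome.tsv")),
       annotations = annotations,
       truth = truth,
       chrom_sizes = unlist(tj$chrom_sizes),
       patients = tj$patients)
}
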