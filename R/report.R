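#' Read a cohort margin table
#'
#' CSV with columns `patient_id, group, r, l, a, p, s, i` (margins in
#' mm, groups `liver` or `pancreatic`).  The packaged reference table
#' from a 12-patient clinical series is available via
#' [example_margin_table()].
#'
#' @param path CSV file path.
#' @return data.frame of class `cohort_margin_table`.
#' @export
read_margin_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "r", "l", "a", "p", "s", "i")
  if (!all(need %in% names(d)))
    stop("margin table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(as.matrix(d[, c("r", "l", "a", "p", "s", "i")]))) ||
      any(d[, c("r", "l", "a", "p", "s", "i")] < 0))
    stop("margins must be finite and non-negative", call. = FALSE)
  class(d) <- c("cohort_margin_table", class(d))
  d
}

#' Packaged reference cohort margins
#'
#' Six-direction ITV margins (mm) for twelve patients (six liver, six
#' pancreatic) from a published clinical ce4DCT series, transcribed as a
#' plain-text fixture.  Used to validate the summary statistics layer.
#'
#' @return a `cohort_margin_table` data.frame.
#' @export
example_margin_table <- function() {
  read_margin_table(system.file("extdata", "cohort_margins.csv",
                                package = "ce4dct", mustWork = TRUE))
}

#' Per-direction margin summary
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' the six directional margins over a patient group, rounded
#' half-away-from-zero to 0.1 mm -- the convention of clinical margin
#' tables.  SD is reported as `NA` for a single patient.
#'
#' @param table a `cohort_margin_table` (see [read_margin_table()]).
#' @param group `"all"`, `"liver"` or `"pancreatic"`.
#' @return data.frame with rows R, L, A, P, S, I and columns
#'   `direction`, `mean`, `sd`, `n`.
#' @export
summarize_margins <- function(table, group = c("all", "liver",
                                               "pancreatic")) {
  group <- match.arg(group)
  d <- if (group == "all") table else table[table$group == group, ]
  if (nrow(d) == 0) stop("no rows in group '", group, "'", call. = FALSE)
  dirs <- c("r", "l", "a", "p", "s", "i")
  data.frame(
    direction = toupper(dirs),
    mean = vapply(dirs, function(x) round_half_away(mean(d[[x]]), 1),
                  numeric(1)),
    sd = vapply(dirs, function(x) {
      if (nrow(d) > 1) round_half_away(stats::sd(d[[x]]), 1) else NA_real_
    }, numeric(1)),
    n = nrow(d),
    row.names = NULL
  )
}

#' Paired t-test
#'
#' Classic paired t on the differences `x - y`: `t = mean(d) /
#' (sd(d)/sqrt(n))`, two-sided p from the t distribution with n-1
#' degrees of freedom.  `x == y` elementwise gives `t = 0, p = 1`;
#' constant non-zero differences have zero variance and are rejected as
#' degenerate.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list `(t, p, df, mean_diff)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
    stop("degenerate t-test: zero-variance non-zero differences",
         call. = FALSE)
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       mean_diff = mean(d))
}

# drop classes/attributes recursively so jsonlite serializes plainly
.plain <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .plain)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.numeric(x) || is.character(x) || is.logical(x)) {
    if (!is.null(dim(x))) x else unname_keep(x)
  } else x
}
unname_keep <- function(x) {
  structure(as.vector(x), names = names(x))
}

#' Structured run report
#'
#' Collects any subset of pipeline outputs (timing record, contrast
#' protocol, kinetics summary, comparison report, margin vector) plus
#' provenance (inputs, config, seed, package version) into a single
#' deterministic structure, serializable as JSON and renderable as
#' markdown.  Field order is fixed; only the `generated` timestamp
#' varies between identical runs.
#'
#' @param timing a `phase_timing` or NULL.
#' @param protocol a `contrast_protocol` or NULL.
#' @param kinetics a `kinetics_summary` or NULL.
#' @param comparison a `comparison_report` or NULL.
#' @param margins a `margin_vector` or NULL.
#' @param config named list of configuration values.
#' @param seed integer seed used, if any.
#' @param timestamp logical; include the wall-clock `generated` field
#'   (disable for byte-identical reports).
#' @return object of class `run_report` with `$json` (list) and
#'   `$markdown` (character vector of lines).
#' @export
run_report <- function(timing = NULL, protocol = NULL, kinetics = NULL,
                       comparison = NULL, margins = NULL,
                       config = list(), seed = NULL, timestamp = TRUE) {
  sections <- list(
    provenance = list(
      package = "ce4dct",
      version = as.character(utils::packageVersion("ce4dct")),
      seed = seed,
      config = config,
      generated = if (timestamp) format(Sys.time(), tz = "UTC") else NULL
    ),
    timing = if (!is.null(timing)) .plain(unclass(timing)),
    protocol = if (!is.null(protocol)) .plain(unclass(protocol)),
    kinetics = if (!is.null(kinetics)) .plain(unclass(kinetics)),
    comparison = if (!is.null(comparison)) .plain(unclass(comparison)),
    margins = if (!is.null(margins))
      as.list(stats::setNames(as.numeric(margins), names(margins)))
  )
  sections <- sections[!vapply(sections, is.null, logical(1))]
  md <- c("# ce4dct run report", "")
  for (nm in names(sections)) {
    md <- c(md, paste0("## ", nm), "")
    sec <- sections[[nm]]
    for (k in names(sec)) {
      v <- sec[[k]]
      if (is.null(v) || is.list(v)) next
      md <- c(md, sprintf("- %s: %s", k, paste(format(v), collapse = ", ")))
    }
    md <- c(md, "")
  }
  structure(list(json = sections, markdown = md), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(x$markdown, sep = "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' @param report a [run_report()].
#' @param json_path,md_path output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
write_run_report <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "run_report"))
  if (!is.null(json_path))
    jsonlite::write_json(report$json, json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  if (!is.null(md_path)) writeLines(report$markdown, md_path)
  invisible(report)
}
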