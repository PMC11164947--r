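# Group-level isotope summary tables: validation, CSV I/O, packaged
# fixtures (basal resources and aboveground invertebrates), rebaselining.
#
# A study table is a data.frame with one row per taxon/material and columns
#   label        free text, unique within the table
#   n            sample count (integer >= 1)
#   d13c_mean    permil vs VPDB
#   d13c_sd      permil >= 0 (NA when a single specimen was measured)
#   d15n_mean    absolute permil vs AIR    \  exactly one of the two is
#   d15n_enrichment  permil vs a baseline  /  populated per row
#   d15n_sd      permil >= 0
#   pct_c, pct_n percent dry mass in [0, 100], optional
#   cn_ratio     dimensionless > 0, optional
# plus any extra columns (e.g. pooled, baseline, species), which are kept.

.iso_numeric_cols <- c(
  "n", "d13c_mean", "d13c_sd", "d15n_mean", "d15n_enrichment", "d15n_sd",
  "pct_c", "pct_n", "cn_ratio"
)

# Typographic minus signs and the permil sign appear in published tables;
# normalize them before numeric conversion.
.normalize_number <- function(x) {
  x <- gsub("−|–", "-", x)
  x <- gsub("‰", "", x)
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Construct and validate a study table
#'
#' @param rows data.frame of group summaries (see column description in
#'   the package source; extra columns are preserved).
#' @param role "source" (basal resources / prey) or "consumer".
#' @param baseline_label optional label of the baseline that rows reporting
#'   `d15n_enrichment` refer to.
#' @return The validated data.frame with class `study_table` and attributes
#'   `role` and `baseline_label`.
#' @export
study_table <- function(rows, role = c("source", "consumer"),
                        baseline_label = NULL) {
  role <- match.arg(role)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  validate_study_table(rows)
  structure(rows,
    class = c("study_table", "data.frame"),
    role = role, baseline_label = baseline_label
  )
}

#' @rdname study_table
#' @export
validate_study_table <- function(rows) {
  need <- c("label", "n", "d13c_mean", "d13c_sd")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("d15n_mean" %in% names(rows)) &&
      !("d15n_enrichment" %in% names(rows))) {
    stop("need a 'd15n_mean' or 'd15n_enrichment' column")
  }
  if (nrow(rows) == 0L) stop("study table has no rows")
  if (anyNA(rows$label) || any(!nzchar(rows$label))) {
    stop("every row needs a non-empty label")
  }
  if (anyDuplicated(rows$label)) {
    stop("duplicated label(s): ",
         paste(unique(rows$label[duplicated(rows$label)]), collapse = ", "))
  }
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    who <- sprintf("row '%s'", row$label)
    if (is.na(row$n) || row$n < 1 || row$n != round(row$n)) {
      stop(who, ": n must be an integer >= 1")
    }
    for (col in intersect(c("d13c_sd", "d15n_sd"), names(rows))) {
      if (!is.na(row[[col]]) && row[[col]] < 0) {
        stop(who, ": ", col, " must be >= 0")
      }
    }
    abs_set <- "d15n_mean" %in% names(rows) && !is.na(row$d15n_mean)
    enr_set <- "d15n_enrichment" %in% names(rows) &&
      !is.na(row$d15n_enrichment)
    if (abs_set == enr_set) {
      stop(who, ": exactly one of d15n_mean / d15n_enrichment must be set")
    }
    for (col in intersect(c("pct_c", "pct_n"), names(rows))) {
      v <- row[[col]]
      if (!is.na(v) && (v < 0 || v > 100)) {
        stop(who, ": ", col, " must lie in [0, 100]")
      }
    }
    if (all(c("pct_c", "pct_n") %in% names(rows)) &&
        !is.na(row$pct_c) && !is.na(row$pct_n) &&
        (row$pct_c <= 0 || row$pct_n <= 0)) {
      stop(who, ": pct_c and pct_n must both be > 0 when both present")
    }
    if ("cn_ratio" %in% names(rows) && !is.na(row$cn_ratio) &&
        row$cn_ratio <= 0) {
      stop(who, ": cn_ratio must be > 0")
    }
  }
  invisible(rows)
}

#' Read a group-level isotope table from CSV
#'
#' Comma-separated, UTF-8, one header row.  Typographic minus signs
#' (U+2212, en dash) and permil signs in numeric cells are accepted; empty
#' cells are parsed as missing, never as zero.
#'
#' @param file path, connection, or a literal string containing newlines.
#' @param role "source" or "consumer".
#' @param baseline_label optional baseline label (defaults to the value of
#'   a `baseline` column when one is present).
#' @return A [study_table()].
#' @export
read_group_table <- function(file, role = c("source", "consumer"),
                             baseline_label = NULL) {
  role <- match.arg(role)
  if (is.character(file) && length(file) == 1L && grepl("\n", file)) {
    file <- textConnection(file)
    on.exit(close(file), add = TRUE)
  }
  raw <- tryCatch(
    utils::read.csv(file,
      stringsAsFactors = FALSE, colClasses = "character",
      fileEncoding = "UTF-8", check.names = TRUE
    ),
    error = function(e) stop("cannot parse input as CSV: ", conditionMessage(e))
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or headerless input")
  for (col in intersect(.iso_numeric_cols, names(raw))) {
    raw[[col]] <- .normalize_number(raw[[col]])
  }
  if ("pooled" %in% names(raw)) {
    pl <- toupper(trimws(raw$pooled))
    raw$pooled <- pl %in% c("1", "TRUE", "T", "YES")
  }
  if (is.null(baseline_label) && "baseline" %in% names(raw)) {
    bl <- unique(raw$baseline[!is.na(raw$baseline)])
    if (length(bl) == 1L) baseline_label <- bl
  }
  study_table(raw, role = role, baseline_label = baseline_label)
}

#' Write a group-level isotope table to CSV
#'
#' Values round-trip exactly through [read_group_table()].
#'
#' @param x a [study_table()] or compatible data.frame.
#' @param file output path or connection.
#' @export
write_group_table <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, na = "")
  invisible(x)
}

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "isoweb")
  if (!nzchar(path)) stop("packaged fixture not found: ", name)
  path
}

#' Packaged basal-resource isotope table
#'
#' Eight rows: six Stipagrostis sabulicola compartments (fresh leaves, dead
#' leaves, fungal-infected dead leaves, root, rhizosheath, soil detritus)
#' and two Acanthosicyos horridus rows (dead-stem litter and soil
#' detritus), with total C/N and absolute delta-13C / delta-15N values.
#'
#' @return A source-role [study_table()].
#' @export
load_table1 <- function() {
  read_group_table(.extdata("table1_basal_resources.csv"), role = "source")
}

#' Packaged aboveground-invertebrate isotope table
#'
#' Fifteen consumer rows with delta-13C (mean +/- SD) and delta-15N
#' enrichment relative to a named baseline (S. sabulicola dead leaves for
#' all taxa except Hycleus zigzagus, whose baseline is the A. horridus dead
#' stem).  Pooled measurements carry `pooled = TRUE` with n set to the
#' number of pooled individuals.
#'
#' @return A consumer-role [study_table()].
#' @export
load_table2 <- function() {
  read_group_table(.extdata("table2_invertebrates.csv"), role = "consumer",
                   baseline_label = "Dead leaves")
}

#' Baseline specification for rebaselining and trophic positions
#'
#' @param label baseline name (e.g. "Dead leaves").
#' @param d15n absolute delta-15N of the baseline, permil.
#' @param d13c optional absolute delta-13C, permil.
#' @param d15n_sd optional SD of the baseline delta-15N, used only when SD
#'   propagation is requested in [rebaseline()].
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(label, d15n, d13c = NULL, d15n_sd = 0) {
  if (!is.finite(d15n)) stop("baseline d15n must be finite")
  if (!is.null(d13c) && !is.finite(d13c)) stop("baseline d13c must be finite")
  if (!is.finite(d15n_sd) || d15n_sd < 0) stop("baseline d15n_sd must be >= 0")
  structure(list(label = label, d15n = d15n, d13c = d13c, d15n_sd = d15n_sd),
            class = "baseline_spec")
}

#' Convert enrichment values to absolute delta-15N (and back)
#'
#' `rebaseline()` turns rows carrying delta-15N enrichment into absolute
#' delta-15N by adding the baseline value; `remove_baseline()` is its exact
#' inverse.  By default the baseline is treated as a fixed constant and row
#' SDs are unchanged; `propagate = TRUE` adds the baseline SD in
#' quadrature.
#'
#' @param x a [study_table()] whose rows carry `d15n_enrichment`
#'   (`rebaseline`) or `d15n_mean` (`remove_baseline`).
#' @param baseline a [baseline_spec()].
#' @param propagate propagate the baseline SD into the row SDs?
#' @return A [study_table()] with the other delta-15N representation.
#' @examples
#' tab <- load_table2()
#' abs <- rebaseline(tab[tab$label == "Zygoribatula sp.", ],
#'                   baseline_spec("Dead leaves", -1.9))
#' abs$d15n_mean # 0.05 + (-1.9) = -1.85
#' @export
rebaseline <- function(x, baseline, propagate = FALSE) {
  stopifnot(inherits(baseline, "baseline_spec"))
  role <- attr(x, "role") %||% "consumer"
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!("d15n_enrichment" %in% names(x)) || anyNA(x$d15n_enrichment)) {
    stop("rows already carry absolute d15n (double-baselining guard); ",
         "expected d15n_enrichment on every row")
  }
  x$d15n_mean <- x$d15n_enrichment + baseline$d15n
  x$d15n_enrichment <- NA_real_
  if (propagate && "d15n_sd" %in% names(x)) {
    x$d15n_sd <- sqrt(ifelse(is.na(x$d15n_sd), 0, x$d15n_sd)^2 +
                        baseline$d15n_sd^2)
  }
  study_table(x, role = role, baseline_label = baseline$label)
}

#' @rdname rebaseline
#' @export
remove_baseline <- function(x, baseline) {
  stopifnot(inherits(baseline, "baseline_spec"))
  role <- attr(x, "role") %||% "consumer"
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!("d15n_mean" %in% names(x)) || anyNA(x$d15n_mean)) {
    stop("rows must carry absolute d15n_mean on every row")
  }
  x$d15n_enrichment <- x$d15n_mean - baseline$d15n
  x$d15n_mean <- NA_real_
  study_table(x, role = role, baseline_label = baseline$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table (%s role, %d rows", attr(x, "role"), nrow(x)))
  if (!is.null(attr(x, "baseline_label"))) {
    cat(sprintf(", baseline: %s", attr(x, "baseline_label")))
  }
  cat(")\n")
  print.data.frame(x, ...)
  invisible(x)
}
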