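# CBC ingestion, the 15-index immune panel, and the health-cohort filters.

#' Canonical names of the 15 immune-related CBC indexes
#'
#' The panel comprises six absolute leukocyte counts (10^9/L), five
#' differential percentages, and four lymphocyte-denominated ratios
#' (NLR, MLR, ELR, BLR). This fixed order is used for every matrix the
#' pipeline produces.
#'
#' @return Character vector of length 15.
#' @export
#' @examples
#' cbc_index_names()
cbc_index_names <- function() {
  c("WBC", "LYMPH", "NEUT", "MONO", "EO", "BASO",
    "LYMPH%", "NEUT%", "MONO%", "EO%", "BASO%",
    "NLR", "MLR", "ELR", "BLR")
}

# Indexes whose population level declines with age; the remaining eleven
# rise with age. This assignment is a fixed constant of the method, not
# re-estimated from data (see spearman_age_direction for the diagnostic).
decreasing_indexes <- function() c("WBC", "LYMPH", "NEUT", "LYMPH%")

#' Direction map of the 15 indexes with respect to age
#'
#' @return Named character vector: `"decreasing_with_age"` for WBC, LYMPH,
#'   NEUT and LYMPH%, `"increasing_with_age"` for the other eleven.
#' @export
index_direction_map <- function() {
  nm <- cbc_index_names()
  setNames(ifelse(nm %in% decreasing_indexes(),
                  "decreasing_with_age", "increasing_with_age"), nm)
}

# Canonical record columns. Counts in 10^9/L, percentages 0-100,
# procalcitonin (pct) in ng/mL.
.count_cols <- c("wbc", "neut", "lymph", "mono", "eo", "baso")
.pct_cols <- c("neut_pct", "lymph_pct", "mono_pct", "eo_pct", "baso_pct")

# Header aliases accepted by read_cbc_table(), keyed by squashed lower-case
# header (non-alphanumerics dropped, "%" mapped to "pct").
.column_aliases <- function() {
  list(
    subject_id = c("subjectid", "id", "sampleid", "subject"),
    age = "age", sex = c("sex", "gender"),
    pct = c("pct", "procalcitonin", "pctngml"),
    wbc = c("wbc", "whitebloodcellcount", "wbccount"),
    neut = c("neut", "neutrophilcount", "neutrophils", "anc"),
    lymph = c("lymph", "lymphocytecount", "lymphocytes", "alc"),
    mono = c("mono", "monocytecount", "monocytes"),
    eo = c("eo", "eos", "eosinophilcount", "eosinophils"),
    baso = c("baso", "basophilcount", "basophils"),
    neut_pct = c("neutpct", "neutrophilpercentage", "neutpercent"),
    lymph_pct = c("lymphpct", "lymphocytepercentage", "lymphpercent"),
    mono_pct = c("monopct", "monocytepercentage", "monopercent"),
    eo_pct = c("eopct", "eosinophilpercentage", "eopercent"),
    baso_pct = c("basopct", "basophilpercentage", "basopercent")
  )
}

.squash_header <- function(x) {
  x <- tolower(x)
  x <- gsub("%", "pct", x, fixed = TRUE)
  gsub("[^a-z0-9]", "", x)
}

#' Read a CBC table from CSV or TSV
#'
#' Reads a delimited file with a header row and maps columns onto the
#' canonical record schema (`subject_id`, `age`, `sex`, `pct` =
#' procalcitonin ng/mL, absolute counts `wbc`, `neut`, `lymph`, `mono`,
#' `eo`, `baso` in 10^9/L, and optional differential percentages).
#' Unparseable numeric cells become `NA` and are counted in a single
#' warning. Columns `age`, `wbc`, `neut` and `lymph` are mandatory.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param col_map Optional named character vector mapping canonical names
#'   to file headers, e.g. `c(wbc = "WBC Count")`. Unmapped columns are
#'   matched against built-in header aliases.
#' @param sep Field separator; inferred from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab-separated).
#' @return A `cbc_cohort` data frame, one row per record.
#' @seealso [as_cbc_cohort()], [apply_health_filters()]
#' @export
read_cbc_table <- function(path, col_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  # read everything as character ("F" for female would otherwise become
  # logical FALSE); numeric coercion happens during canonicalization
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = c("", "NA", "NaN", "N/A", "null"))
  as_cbc_cohort(raw, col_map = col_map)
}

#' Coerce a data frame of raw CBC measurements to a cohort object
#'
#' Canonicalizes column names, coerces measurement columns to numeric
#' (counting unparseable cells), validates ranges (counts non-negative,
#' percentages within 0-100), derives missing percentages from counts,
#' and reconciles supplied percentages against counts: when a supplied
#' percentage disagrees with `100 * count / wbc` by more than
#' `consistency_tol` percentage points, the count-derived value wins and
#' a warning is issued (counts are the primary measurement).
#'
#' @param df A data frame.
#' @param col_map Optional named character vector, see [read_cbc_table()].
#' @param consistency_tol Tolerance in percentage points for the
#'   count/percentage consistency check (default 0.5).
#' @return A `cbc_cohort` data frame.
#' @export
as_cbc_cohort <- function(df, col_map = NULL, consistency_tol = 0.5) {
  headers <- names(df)
  squashed <- .squash_header(headers)
  aliases <- .column_aliases()
  mapping <- character(0)
  for (canon in names(aliases)) {
    if (!is.null(col_map) && canon %in% names(col_map)) {
      hit <- match(col_map[[canon]], headers)
      if (is.na(hit)) stop("mapped column not found in file: ", col_map[[canon]])
    } else {
      hit <- match(TRUE, squashed %in% aliases[[canon]])
    }
    if (!is.na(hit)) mapping[[canon]] <- headers[[hit]]
  }
  mandatory <- c("age", "wbc", "neut", "lymph")
  missing <- setdiff(mandatory, names(mapping))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }

  n <- nrow(df)
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(mapping)) {
      as.character(df[[mapping[["subject_id"]]]])
    } else sprintf("S%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  out$sex <- if ("sex" %in% names(mapping)) {
    s <- tolower(as.character(df[[mapping[["sex"]]]]))
    s[s %in% c("m", "male", "1")] <- "male"
    s[s %in% c("f", "female", "2", "0")] <- "female"
    s[!s %in% c("male", "female")] <- "unknown"
    s
  } else rep("unknown", n)

  n_bad <- 0L
  to_num <- function(x) {
    if (is.numeric(x)) return(x)
    v <- suppressWarnings(as.numeric(as.character(x)))
    n_bad <<- n_bad + sum(is.na(v) & !is.na(x) & as.character(x) != "")
    v
  }
  numeric_cols <- c("age", "pct", .count_cols, .pct_cols)
  for (canon in numeric_cols) {
    out[[canon]] <- if (canon %in% names(mapping)) {
      to_num(df[[mapping[[canon]]]])
    } else NA_real_
  }
  if (n_bad > 0L) {
    warning(sprintf("%d unparseable numeric cell(s) set to NA", n_bad))
  }

  for (cc in c(.count_cols, "pct")) {
    bad <- which(out[[cc]] < 0)
    if (length(bad)) stop("negative values in column '", cc, "'")
  }
  for (pc in .pct_cols) {
    bad <- which(out[[pc]] < 0 | out[[pc]] > 100)
    if (length(bad)) stop("percentages outside [0,100] in column '", pc, "'")
  }

  # Reconcile or derive percentages from counts (counts are primary).
  n_inconsistent <- 0L
  for (i in seq_along(.pct_cols)) {
    pc <- .pct_cols[[i]]
    cc <- .count_cols[[i + 1L]]  # skip wbc
    derived <- 100 * out[[cc]] / out$wbc
    have <- !is.na(out[[pc]]) & !is.na(derived)
    off <- have & abs(out[[pc]] - derived) > consistency_tol
    n_inconsistent <- n_inconsistent + sum(off)
    out[[pc]][off] <- derived[off]
    fill <- is.na(out[[pc]]) & !is.na(derived)
    out[[pc]][fill] <- derived[fill]
  }
  if (n_inconsistent > 0L) {
    warning(sprintf(paste0("%d percentage cell(s) disagreed with counts by > ",
                           "%.2f points; count-derived values used"),
                    n_inconsistent, consistency_tol))
  }
  class(out) <- c("cbc_cohort", "data.frame")
  out
}

#' Derive the 15-index immune panel from one CBC record
#'
#' Ratios are always recomputed from the absolute counts
#' (NLR = NEUT/LYMPH, MLR = MONO/LYMPH, ELR = EO/LYMPH, BLR = BASO/LYMPH);
#' percentages are taken from the record when present and otherwise derived
#' as `100 * count / WBC`.
#'
#' @param record A single-row `cbc_cohort` data frame (or 1-row data frame
#'   with canonical columns).
#' @return Named numeric vector of length 15 in [cbc_index_names()] order.
#' @export
#' @examples
#' rec <- data.frame(wbc = 6, neut = 4, lymph = 2, mono = 0.6,
#'                   eo = 0.15, baso = 0.03)
#' derive_panel(rec)[c("NLR", "MONO%")]
derive_panel <- function(record) {
  stopifnot(nrow(record) == 1L)
  drop(derive_panels(record))
}

#' Derive the 15-index panel for every record in a cohort
#'
#' @param records A `cbc_cohort` data frame.
#' @return Numeric matrix, `nrow(records)` x 15, columns in
#'   [cbc_index_names()] order, rownames = subject ids when available.
#' @export
derive_panels <- function(records) {
  nm <- cbc_index_names()
  if (nrow(records) == 0L) {
    return(matrix(numeric(0), 0L, 15L, dimnames = list(NULL, nm)))
  }
  need <- c("wbc", "neut", "lymph")
  for (cc in need) {
    if (is.null(records[[cc]]) || anyNA(records[[cc]])) {
      stop("missing values in mandatory count column '", cc, "'")
    }
  }
  if (any(records$lymph <= 0) || any(records$wbc <= 0)) {
    stop("undefined ratio: LYMPH and WBC must be positive for every record")
  }
  cnt <- function(cc) {
    v <- records[[cc]]
    if (is.null(v)) rep(NA_real_, nrow(records)) else v
  }
  pct_or_derived <- function(pc, cc) {
    v <- if (is.null(records[[pc]])) rep(NA_real_, nrow(records)) else records[[pc]]
    miss <- is.na(v)
    v[miss] <- 100 * cnt(cc)[miss] / records$wbc[miss]
    v
  }
  out <- cbind(
    "WBC" = records$wbc, "LYMPH" = records$lymph, "NEUT" = records$neut,
    "MONO" = cnt("mono"), "EO" = cnt("eo"), "BASO" = cnt("baso"),
    "LYMPH%" = pct_or_derived("lymph_pct", "lymph"),
    "NEUT%" = pct_or_derived("neut_pct", "neut"),
    "MONO%" = pct_or_derived("mono_pct", "mono"),
    "EO%" = pct_or_derived("eo_pct", "eo"),
    "BASO%" = pct_or_derived("baso_pct", "baso"),
    "NLR" = records$neut / records$lymph,
    "MLR" = cnt("mono") / records$lymph,
    "ELR" = cnt("eo") / records$lymph,
    "BLR" = cnt("baso") / records$lymph
  )[, nm, drop = FALSE]
  if (!is.null(records$subject_id)) rownames(out) <- records$subject_id
  out
}

#' Screen a cohort with the inflammation and reference-range filters
#'
#' A record is retained iff age lies in `age_range`, procalcitonin does not
#' exceed `pct_max` ng/mL (a marker of bacterial infection), and WBC, NEUT,
#' LYMPH, NEUT% and LYMPH% all fall inside their clinical reference ranges.
#' All retention intervals are closed; the procalcitonin exclusion is
#' strict (`> pct_max` rejects). Each rejected record is attributed to the
#' first failing rule in the fixed order age, PCT, WBC, NEUT, LYMPH,
#' NEUT%, LYMPH%, so rejection counts are reproducible.
#'
#' @param records A `cbc_cohort` data frame.
#' @param age_range,wbc_range,neut_range,lymph_range,neut_pct_range,lymph_pct_range
#'   Closed retention intervals. Defaults: age 20-84 y, WBC 4-10 and NEUT
#'   2-7 and LYMPH 0.8-4 (10^9/L), NEUT% 40-75, LYMPH% 20-50.
#' @param pct_max Procalcitonin threshold, ng/mL (default 0.5).
#' @param missing_pct `"retain"` (default) keeps records without a
#'   procalcitonin value and warns; `"reject"` drops them (reason `"PCT"`).
#' @return A `filter_report`: list with `retained` (a `cbc_cohort`),
#'   `rejected` (records plus a `reason` column), `counts` (rejections by
#'   reason) and `n_input`.
#' @export
apply_health_filters <- function(records,
                                 age_range = c(20, 84),
                                 pct_max = 0.5,
                                 wbc_range = c(4, 10),
                                 neut_range = c(2, 7),
                                 lymph_range = c(0.8, 4),
                                 neut_pct_range = c(40, 75),
                                 lymph_pct_range = c(20, 50),
                                 missing_pct = c("retain", "reject")) {
  missing_pct <- match.arg(missing_pct)
  panels <- derive_panels(records)
  n <- nrow(records)
  in_range <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]

  pct_fail <- !is.na(records$pct) & records$pct > pct_max
  pct_miss <- is.na(records$pct)
  if (missing_pct == "reject") {
    pct_fail <- pct_fail | pct_miss
  } else if (any(pct_miss)) {
    warning(sprintf("%d record(s) lack procalcitonin; retained (missing_pct = 'retain')",
                    sum(pct_miss)))
  }

  # Fixed rule order; the first failing rule names the rejection reason.
  rules <- list(
    age = !in_range(records$age, age_range),
    PCT = pct_fail,
    WBC = !in_range(panels[, "WBC"], wbc_range),
    NEUT = !in_range(panels[, "NEUT"], neut_range),
    LYMPH = !in_range(panels[, "LYMPH"], lymph_range),
    `NEUT%` = !in_range(panels[, "NEUT%"], neut_pct_range),
    `LYMPH%` = !in_range(panels[, "LYMPH%"], lymph_pct_range)
  )
  reason <- rep(NA_character_, n)
  for (rn in names(rules)) {
    hit <- is.na(reason) & rules[[rn]]
    reason[hit] <- rn
  }
  keep <- is.na(reason)
  rejected <- as.data.frame(records)[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  retained <- records[keep, , drop = FALSE]
  class(retained) <- c("cbc_cohort", "data.frame")
  counts <- table(factor(reason[!keep], levels = names(rules)))
  structure(list(retained = retained, rejected = rejected,
                 counts = counts, n_input = n),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("CBC health filter report: %d in, %d retained, %d rejected\n",
              x$n_input, nrow(x$retained), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    cat("rejections by first failing rule:\n")
    print(x$counts[x$counts > 0])
  }
  invisible(x)
}

#' Summarize a cohort by sex and age band
#'
#' Age bands follow the young (20-40), middle-aged (41-60) and old (> 60)
#' convention.
#'
#' @param records A `cbc_cohort` data frame.
#' @return Data frame with columns `group`, `level`, `n`, `pct`.
#' @export
cohort_summary <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(data.frame(group = character(0), level = character(0),
                      n = integer(0), pct = numeric(0)))
  }
  sex_tab <- table(factor(records$sex, levels = c("male", "female", "unknown")))
  band <- cut(records$age, breaks = c(-Inf, 40, 60, Inf),
              labels = c("young (20-40)", "middle-aged (41-60)", "old (>60)"))
  band_tab <- table(band)
  rows <- rbind(
    data.frame(group = "sex", level = names(sex_tab),
               n = as.integer(sex_tab), stringsAsFactors = FALSE),
    data.frame(group = "age_band", level = names(band_tab),
               n = as.integer(band_tab), stringsAsFactors = FALSE)
  )
  rows$pct <- 100 * rows$n / n
  rows
}
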