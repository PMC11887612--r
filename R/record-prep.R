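#' Prepartum body mass index
#'
#' @param height_cm maternal height in centimetres.
#' @param prepreg_weight_kg prepregnancy weight in kilograms.
#' @return BMI in kg/m^2; \code{NA} where either input is missing or
#'   non-positive (such records are later dropped by
#'   \code{\link{filter_records}}, never raised as an error).
#' @examples
#' derive_bmi(160, 64)    # 25.0
#' @export
derive_bmi <- function(height_cm, prepreg_weight_kg) {
  out <- prepreg_weight_kg / (height_cm / 100)^2
  out[!is.finite(out) | height_cm <= 0 | prepreg_weight_kg <= 0] <- NA_real_
  out
}

#' Gestational weight gain corrected to 40 weeks
#'
#' Raw gain (delivery weight minus prepregnancy weight) is rescaled
#' proportionally by \code{40 / gestation_weeks}, the linear correction that
#' maps zero gain to zero and reproduces the observed gain at a 40-week
#' gestation.
#'
#' @param prepreg_weight_kg,delivery_weight_kg weights in kilograms.
#' @param gestation_weeks obstetric estimate of gestation length in weeks.
#' @return Adjusted GWG in kg; \code{NA} where any input is missing or
#'   gestation is non-positive. Negative gain (weight loss) is preserved.
#' @examples
#' adjust_gwg(60, 74, 40)   # 14
#' adjust_gwg(60, 74, 35)   # 16
#' @export
adjust_gwg <- function(prepreg_weight_kg, delivery_weight_kg, gestation_weeks) {
  out <- (delivery_weight_kg - prepreg_weight_kg) * (40 / gestation_weeks)
  out[!is.finite(out) | gestation_weeks <= 0] <- NA_real_
  out
}

#' Classify BMI and GWG as optimal / non-optimal
#'
#' Binary mediator coding: \code{m1 = 1} for optimal prepartum BMI, 2
#' otherwise; \code{m2 = 1} for optimal adjusted GWG, 2 otherwise. The
#' default optimal intervals follow the Institute of Medicine guidance for
#' normal-weight women: BMI in [18.5, 25) and a 40-week gain of [11.5, 16] kg.
#' Boundary conventions are configurable because "18.5 to 25" leaves the
#' upper endpoint ambiguous; the default excludes BMI = 25 (IOM's upper
#' normal is 24.9) and includes both GWG endpoints.
#'
#' @param bmi prepartum BMI in kg/m^2 (vectorised).
#' @param gwg_adj 40-week adjusted GWG in kg (vectorised).
#' @param bmi_range,gwg_range numeric length-2 optimal intervals.
#' @param bmi_upper_inclusive,gwg_upper_inclusive logical; whether the upper
#'   endpoint belongs to the optimal class.
#' @return A list with integer vectors \code{m1} and \code{m2}.
#' @examples
#' classify_mediators(22, 12)     # m1 = 1, m2 = 1
#' classify_mediators(25, 16)     # m1 = 2, m2 = 1
#' @export
classify_mediators <- function(bmi, gwg_adj,
                               bmi_range = c(18.5, 25.0),
                               gwg_range = c(11.5, 16.0),
                               bmi_upper_inclusive = FALSE,
                               gwg_upper_inclusive = TRUE) {
  in_range <- function(v, rng, upper_inc)
    v >= rng[1] & (if (upper_inc) v <= rng[2] else v < rng[2])
  list(m1 = ifelse(in_range(bmi, bmi_range, bmi_upper_inclusive), 1L, 2L),
       m2 = ifelse(in_range(gwg_adj, gwg_range, gwg_upper_inclusive), 1L, 2L))
}

outcome_fields <- function() c("gest_htn", "htn_eclampsia", "induction", "cesarean", "icu")
anthro_fields <- function() c("height", "prepreg_weight", "delivery_weight", "gestation_weeks")

#' Read record-level birth data
#'
#' Reads delimited text with one row per singleton birth. Canonical column
#' names are \code{race_class} (1 = non-Black, 2 = Black), \code{height},
#' \code{prepreg_weight}, \code{delivery_weight}, \code{gestation_weeks} and
#' the five outcome flags \code{gest_htn}, \code{htn_eclampsia},
#' \code{induction}, \code{cesarean}, \code{icu} (0/1). Other headers are
#' mapped via \code{col_map}. Empty fields and any value in \code{sentinels}
#' are read as missing; vital-statistics files conventionally use 999-style
#' unknown codes.
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected from the
#'   extension, or set \code{sep}).
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names, e.g. \code{c(height = "MHTR")}.
#' @param units \code{"metric"} (cm/kg, the canonical form) or
#'   \code{"imperial"} (inches/pounds, converted at read time with
#'   1 in = 2.54 cm, 1 lb = 0.45359237 kg).
#' @param sentinels numeric codes to treat as missing in every numeric field.
#' @param sep field separator; default inferred from the file extension.
#' @return A data frame of birth records in canonical columns and units.
#' @export
read_birth_records <- function(path, col_map = NULL,
                               units = c("metric", "imperial"),
                               sentinels = c(999, 9999, 99.9),
                               sep = NULL) {
  units <- match.arg(units)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  canonical <- c("race_class", anthro_fields(), outcome_fields())
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop("mapped column not found in file: ", col_map[[canon]])
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(canonical, names(df))
  if (length(missing_cols))
    stop("input is missing required columns: ", paste(missing_cols, collapse = ", "))
  df <- df[canonical]
  for (f in canonical) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- !is.na(df[[f]]) & is.na(v)
    if (any(bad))
      stop("unparsable value in column '", f, "' at row ", which(bad)[1L])
    v[v %in% sentinels] <- NA_real_
    df[[f]] <- v
  }
  if (anyNA(df$race_class) || !all(df$race_class %in% 1:2))
    stop("race_class must be 1 (non-Black) or 2 (Black) and never missing")
  if (units == "imperial") {
    df$height <- df$height * 2.54
    for (f in c("prepreg_weight", "delivery_weight"))
      df[[f]] <- df[[f]] * 0.45359237
  }
  df
}

#' Apply missingness deletions and derive mediator classes
#'
#' Replicates the two-stage deletion protocol: first drop any record missing
#' one or more of the five outcome flags, then drop any record missing (or
#' with non-positive) height, prepregnancy weight, delivery weight or
#' gestation weeks. Survivors carry derived BMI, adjusted GWG and mediator
#' classes. No plausibility trimming is applied: extreme but non-missing
#' values are retained.
#'
#' @param records data frame in the canonical layout of
#'   \code{\link{read_birth_records}}.
#' @param ... classification options passed to \code{\link{classify_mediators}}.
#' @return A list of class \code{"prepared_records"} with components
#'   \code{records} (retained rows plus \code{bmi}, \code{gwg_adj},
#'   \code{m1}, \code{m2}) and \code{log} (a \code{deletion_log}).
#' @export
filter_records <- function(records, ...) {
  n_input <- nrow(records)
  has_outcomes <- !Reduce(`|`, lapply(outcome_fields(), function(f) is.na(records[[f]])))
  records <- records[has_outcomes, , drop = FALSE]
  n_out_del <- n_input - nrow(records)

  bmi <- derive_bmi(records$height, records$prepreg_weight)
  gwg <- adjust_gwg(records$prepreg_weight, records$delivery_weight,
                    records$gestation_weeks)
  ok <- !is.na(bmi) & !is.na(gwg)
  n_anthro_del <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  records$bmi <- bmi[ok]
  records$gwg_adj <- gwg[ok]
  cls <- classify_mediators(records$bmi, records$gwg_adj, ...)
  records$m1 <- cls$m1
  records$m2 <- cls$m2
  rownames(records) <- NULL
  structure(list(records = records,
                 log = deletion_log(n_input, n_out_del, n_anthro_del)),
            class = "prepared_records")
}

#' Deletion log
#'
#' @param input number of input records.
#' @param missing_outcome records deleted for a missing outcome flag.
#' @param missing_anthro records deleted for missing anthropometric data.
#' @return A \code{"deletion_log"} list with the three counts and the implied
#'   \code{retained} count.
#' @export
deletion_log <- function(input, missing_outcome, missing_anthro) {
  retained <- input - missing_outcome - missing_anthro
  stopifnot(retained >= 0)
  structure(list(input = input, missing_outcome = missing_outcome,
                 missing_anthro = missing_anthro, retained = retained),
            class = "deletion_log")
}

#' @export
print.deletion_log <- function(x, ...) {
  pct <- function(k) if (x$input > 0) sprintf(" (%.1f%%)", 100 * k / x$input) else ""
  cat(sprintf("Input records:               %s\n", format(x$input, big.mark = ",")))
  cat(sprintf("Deleted, missing outcome:    %s%s\n",
              format(x$missing_outcome, big.mark = ","), pct(x$missing_outcome)))
  cat(sprintf("Deleted, missing BMI/GWG:    %s%s\n",
              format(x$missing_anthro, big.mark = ","), pct(x$missing_anthro)))
  cat(sprintf("Retained for modelling:      %s\n", format(x$retained, big.mark = ",")))
  invisible(x)
}

#' @export
print.prepared_records <- function(x, ...) {
  print(x$log)
  cat(sprintf("Columns: %s\n", paste(names(x$records), collapse = ", ")))
  invisible(x)
}

#' Aggregate prepared records to the eight-cell count table
#'
#' @param prepared a \code{prepared_records} object from
#'   \code{\link{filter_records}}, or its \code{$records} data frame
#'   (must carry \code{race_class}, \code{m1}, \code{m2} and the outcome).
#' @param outcome name of the outcome column to count, one of
#'   \code{gest_htn}, \code{htn_eclampsia}, \code{induction},
#'   \code{cesarean}, \code{icu}.
#' @return A \code{\link{cell_counts}} table; empty cells are zero-filled.
#' @export
aggregate_cells <- function(prepared, outcome) {
  df <- if (inherits(prepared, "prepared_records")) prepared$records else prepared
  if (!outcome %in% names(df)) stop("no such outcome column: ", outcome)
  full <- expand.grid(m2 = 1:2, m1 = 1:2, x = 1:2)
  if (nrow(df) == 0L)
    return(cell_counts(full$x, full$m1, full$m2, rep(0, 8), rep(0, 8), outcome))
  key <- factor(paste(df$race_class, df$m1, df$m2),
                levels = paste(full$x, full$m1, full$m2))
  if (anyNA(key)) stop("records carry cell indices outside {1,2}")
  n <- tabulate(key, nbins = 8L)
  r <- vapply(split(df[[outcome]], key), sum, numeric(1))
  cell_counts(full$x, full$m1, full$m2, r, n, outcome)
}
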