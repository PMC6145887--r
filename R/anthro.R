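#' One child's sparse anthropometry record
#'
#' Visit-level weight and recumbent length for one child, with sex and
#' strictly increasing visit ages (at most one visit per age).
#'
#' @param child_id identifier.
#' @param sex `"male"` or `"female"`.
#' @param visits data.frame with columns `age_days`, `weight_kg`,
#'   `length_cm`; positive measurements, increasing ages.
#' @return an object of class `anthro_record`.
#' @export
anthro_record <- function(child_id, sex, visits) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.data.frame(visits),
            all(c("age_days", "weight_kg", "length_cm") %in% names(visits)))
  if (nrow(visits) == 0L) stop_invalid("child %s: empty visit list", child_id)
  if (anyDuplicated(visits$age_days)) stop_invalid("child %s: duplicate visit age", child_id)
  if (is.unsorted(visits$age_days, strictly = TRUE)) {
    visits <- visits[order(visits$age_days), ]
  }
  if (any(visits$weight_kg <= 0) || any(visits$length_cm <= 0)) {
    stop_invalid("child %s: weight and length must be positive", child_id)
  }
  structure(list(child_id = as.character(child_id), sex = sex,
                 visits = visits[, c("age_days", "weight_kg", "length_cm")]),
            class = "anthro_record")
}

#' @export
print.anthro_record <- function(x, ...) {
  cat(sprintf("Child %s (%s): %d visits, ages %s days\n", x$child_id, x$sex,
              nrow(x$visits), paste(x$visits$age_days, collapse = ", ")))
  invisible(x)
}

#' Weight-for-length growth index
#'
#' The curve-valued outcome for children under two: weight (kg) divided by
#' recumbent length (cm) at each visit, in visit order.
#'
#' @param record an `anthro_record`.
#' @return data.frame with `age_days` and `index`.
#' @export
growth_index <- function(record) {
  stopifnot(inherits(record, "anthro_record"))
  data.frame(age_days = record$visits$age_days,
             index = record$visits$weight_kg / record$visits$length_cm)
}

#' Read / write long-format anthropometry CSV
#'
#' Columns: child_id, sex, age_days, weight_kg, length_cm.
#'
#' @param path CSV path.
#' @return for the reader, a list of `anthro_record`.
#' @export
read_anthro <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("child_id", "sex", "age_days", "weight_kg", "length_cm")
  if (!all(need %in% names(df))) {
    stop_invalid("anthropometry CSV must have columns %s", paste(need, collapse = ", "))
  }
  lapply(split(df, df$child_id)[unique(df$child_id)], function(d) {
    anthro_record(d$child_id[1], d$sex[1], d[, c("age_days", "weight_kg", "length_cm")])
  })
}

#' @rdname read_anthro
#' @param records list of `anthro_record`.
#' @export
write_anthro <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(child_id = r$child_id, sex = r$sex, r$visits)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a growth-reference CSV
#'
#' Columns: sex, age_days, L, M, S, optionally `measure`.
#'
#' @param path CSV path.
#' @param measure when the file carries a `measure` column, keep only rows
#'   for this measure.
#' @return a `growth_reference` data.frame.
#' @export
read_reference <- function(path, measure = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(measure) && "measure" %in% names(df)) {
    df <- df[df$measure == measure, setdiff(names(df), "measure")]
  }
  need <- c("sex", "age_days", "L", "M", "S")
  if (!all(need %in% names(df))) {
    stop_invalid("reference CSV must have columns %s", paste(need, collapse = ", "))
  }
  class(df) <- c("growth_reference", "data.frame")
  df
}

#' @rdname read_reference
#' @param reference a `growth_reference`.
#' @export
write_reference <- function(reference, path) {
  write.csv(as.data.frame(reference), path, row.names = FALSE)
  invisible(path)
}

#' LMS z-score
#'
#' The skew-normalizing growth-standard transform:
#' `z = ((X/M)^L - 1) / (L * S)` when `L != 0`, and `log(X/M) / S` in the
#' `L -> 0` limit. L, M and S are looked up per sex and age, with optional
#' linear interpolation between bracketing tabulated ages.
#'
#' @param value measurement (same units as the reference M).
#' @param age_days age at measurement.
#' @param sex `"male"` or `"female"`.
#' @param reference a `growth_reference`.
#' @param interpolate linearly interpolate L, M, S in age (default TRUE).
#' @return z-score(s); vectorized over `value`/`age_days`.
#' @export
lms_zscore <- function(value, age_days, sex, reference, interpolate = TRUE) {
  stopifnot(inherits(reference, "growth_reference"))
  sex <- match.arg(sex, c("male", "female"))
  ref <- reference[reference$sex == sex, ]
  ref <- ref[order(ref$age_days), ]
  rng <- range(ref$age_days)
  if (any(age_days < rng[1] - 1e-9 | age_days > rng[2] + 1e-9)) {
    stop_invalid("age %s outside reference range [%g, %g]",
                 paste(age_days[age_days < rng[1] | age_days > rng[2]], collapse = ","),
                 rng[1], rng[2])
  }
  lookup <- function(col) {
    if (interpolate) {
      approx(ref$age_days, ref[[col]], age_days)$y
    } else {
      ref[[col]][vapply(age_days, function(a) which.min(abs(ref$age_days - a)), 1L)]
    }
  }
  L <- lookup("L"); M <- lookup("M"); S <- lookup("S")
  ifelse(abs(L) < 1e-7,
         log(value / M) / S,
         ((value / M)^L - 1) / (L * S))
}

#' Conditional weight gain (CWG) z-scores
#'
#' Standardized residuals from an ordinary least-squares regression of WAZ
#' at six months on WAZ at birth, with LAZ at both occasions and the
#' precise age at the six-month visit as covariates. By construction the
#' scores have sample mean 0 and standard deviation 1; a score >= 0
#' defines rapid infant weight gain.
#'
#' @param waz_birth,waz_6m weight-for-age z-scores at birth and six months.
#' @param laz_birth,laz_6m length-for-age z-scores at the two occasions.
#' @param age_6m precise age (days) at the six-month visit.
#' @param child_id optional ids (default index).
#' @param use_laz which LAZ occasions enter the design:
#'   `"both"` (default), `"birth"`, or `"6m"` — the published description
#'   lists "LAZ and precise age" without enumerating occasions.
#' @return object of class `cwg` : data.frame with `child_id`, `cwg_z`,
#'   `rapid`, plus the fitted regression and design metadata as attributes.
#' @export
cwg_zscores <- function(waz_birth, waz_6m, laz_birth, laz_6m, age_6m,
                        child_id = NULL, use_laz = c("both", "birth", "6m")) {
  use_laz <- match.arg(use_laz)
  n <- length(waz_6m)
  stopifnot(length(waz_birth) == n, length(age_6m) == n)
  if (is.null(child_id)) child_id <- as.character(seq_len(n))
  X <- switch(use_laz,
              both  = cbind(waz_birth = waz_birth, laz_birth = laz_birth,
                            laz_6m = laz_6m, age_6m = age_6m),
              birth = cbind(waz_birth = waz_birth, laz_birth = laz_birth,
                            age_6m = age_6m),
              `6m`  = cbind(waz_birth = waz_birth, laz_6m = laz_6m,
                            age_6m = age_6m))
  ok <- stats::complete.cases(cbind(waz_6m, X))
  if (sum(ok) < ncol(X) + 2L) {
    stop_invalid("need at least %d children with complete values, have %d",
                 ncol(X) + 2L, sum(ok))
  }
  Xd <- cbind(`(Intercept)` = 1, X[ok, , drop = FALSE])
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xd))]]
    stop_invalid("singular design: collinear columns %s", paste(bad, collapse = ", "))
  }
  fit <- lm.fit(Xd, waz_6m[ok])
  res <- fit$residuals
  s <- sd(res)
  if (s < 1e-12) {
    stop_invalid("degenerate fit: residual standard deviation is zero")
  }
  z <- res / s
  out <- data.frame(child_id = child_id[ok], cwg_z = z, rapid = z >= 0,
                    stringsAsFactors = FALSE)
  attr(out, "coefficients") <- fit$coefficients
  attr(out, "design") <- colnames(Xd)
  attr(out, "use_laz") <- use_laz
  attr(out, "n") <- sum(ok)
  class(out) <- c("cwg", "data.frame")
  out
}

#' @export
print.cwg <- function(x, ...) {
  cat(sprintf("Conditional weight gain scores for %d children\n", attr(x, "n")))
  cat(sprintf("  design: WAZ6 ~ %s\n", paste(attr(x, "design")[-1], collapse = " + ")))
  cat(sprintf("  rapid (CWG >= 0): %d | non-rapid: %d\n",
              sum(x$rapid), sum(!x$rapid)))
  invisible(x)
}

#' @export
summary.cwg <- function(object, ...) {
  cat(sprintf("CWG z-scores: mean %.2e, sd %.6f (mean 0, sd 1 by construction)\n",
              mean(object$cwg_z), sd(object$cwg_z)))
  print(attr(object, "coefficients"))
  invisible(object)
}

#' Partition children into rapid vs non-rapid weight gain
#'
#' Rapid infant weight gain is CWG >= 0 (boundary inclusive).
#'
#' @param cwg a `cwg` object (or data.frame with `child_id`, `cwg_z`).
#' @return list with character vectors `rapid` and `non_rapid`.
#' @export
classify_rapid <- function(cwg) {
  list(rapid = cwg$child_id[cwg$cwg_z >= 0],
       non_rapid = cwg$child_id[cwg$cwg_z < 0])
}

#' CWG scores straight from anthropometry records
#'
#' Convenience wrapper: extracts WAZ/LAZ at birth and the visit nearest six
#' months (within `window` days) for every child with both visits, then
#' calls [cwg_zscores()].
#'
#' @param records list of `anthro_record`.
#' @param reference_weight,reference_length `growth_reference` tables.
#' @param target_6m nominal six-month age in days.
#' @param window tolerance around `target_6m` (days).
#' @inheritParams cwg_zscores
#' @return a `cwg` object.
#' @export
cwg_from_records <- function(records, reference_weight, reference_length,
                             target_6m = 182, window = 120,
                             use_laz = c("both", "birth", "6m")) {
  rows <- lapply(records, function(r) {
    v <- r$visits
    if (abs(v$age_days[1]) > 1e-9) return(NULL)      # need a birth visit
    cand <- which(abs(v$age_days - target_6m) <= window & v$age_days > 0)
    if (!length(cand)) return(NULL)
    i6 <- cand[which.min(abs(v$age_days[cand] - target_6m))]
    data.frame(
      child_id = r$child_id,
      waz_birth = lms_zscore(v$weight_kg[1], 0, r$sex, reference_weight),
      laz_birth = lms_zscore(v$length_cm[1], 0, r$sex, reference_length),
      waz_6m = lms_zscore(v$weight_kg[i6], v$age_days[i6], r$sex, reference_weight),
      laz_6m = lms_zscore(v$length_cm[i6], v$age_days[i6], r$sex, reference_length),
      age_6m = v$age_days[i6])
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) < 6L) stop_invalid("too few children with birth and six-month visits")
  cwg_zscores(df$waz_birth, df$waz_6m, df$laz_birth, df$laz_6m, df$age_6m,
              child_id = df$child_id, use_laz = match.arg(use_laz))
}
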