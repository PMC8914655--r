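#' Measurement agreement statistics
#'
#' Repeatability and between-device agreement for repeated hand
#' measurements.  A measurement session is the set of repeated values of
#' one hand part, by one device, for one participant (default 15
#' repetitions).  Three statistics summarise the sessions:
#'
#' * pooled repeatability SD — per participant, the sample standard
#'   deviation (denominator n - 1) over that participant's repeats;
#'   reported as the mean of the per-participant SDs across participants
#'   (`method = "mean"`, the default).  `method = "pooled"` instead takes
#'   one sample SD over all values of all participants, each centred on
#'   its own participant mean.
#' * difference of means (DM) — for one hand part measured by two devices,
#'   the average over shared participants of the absolute difference
#'   between the two per-participant means.
#' * Pearson correlation between paired per-repetition values of two
#'   devices within one measure family (lengths; angles).
#'
#' @name agreement
NULL

check_sessions <- function(values, participant) {
  stopifnot(length(values) == length(participant))
  n_per <- table(participant)
  if (any(n_per < 2)) {
    stop("every participant needs at least 2 repeated values for an SD ",
         "(violated by: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), ")",
         call. = FALSE)
  }
}

#' Pooled repeatability standard deviation
#'
#' @param values numeric measurements (one device, one hand part).
#' @param participant participant label per value.
#' @param method `"mean"` (default): mean over participants of
#'   per-participant sample SDs.  `"pooled"`: single sample SD of all
#'   values after centring each on its participant mean (pooled across the
#'   whole 5 x 15 table).
#' @return SD in the unit of the measurements.
#' @export
pooled_sd <- function(values, participant, method = c("mean", "pooled")) {
  method <- match.arg(method)
  check_sessions(values, participant)
  by_p <- split(values, participant)
  if (method == "mean") {
    mean(vapply(by_p, stats::sd, numeric(1)))
  } else {
    centred <- unlist(lapply(by_p, function(v) v - mean(v)))
    sqrt(sum(centred^2) / (length(centred) - 1))
  }
}

#' Difference of means between two devices
#'
#' `DM = (1/Np) * sum_p |mean_A(p) - mean_B(p)|` over the participants
#' shared by both devices.
#'
#' @param values_a,participant_a measurements and participant labels from
#'   device A (one hand part).
#' @param values_b,participant_b same for device B.
#' @return DM in the unit of the measurements.
#' @export
difference_of_means <- function(values_a, participant_a,
                                values_b, participant_b) {
  ma <- tapply(values_a, participant_a, mean)
  mb <- tapply(values_b, participant_b, mean)
  shared <- intersect(names(ma), names(mb))
  if (length(shared) == 0) {
    stop("the two devices share no participants", call. = FALSE)
  }
  mean(abs(ma[shared] - mb[shared]))
}

#' Pearson correlation between paired measurements
#'
#' Standard product-moment correlation of paired values (e.g. the pooled
#' per-repetition values of one measure family from two devices).
#'
#' @param x,y paired numeric vectors, at least 3 pairs, each with nonzero
#'   variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop("Pearson correlation needs at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation is undefined for zero-variance input",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Agreement report for two result tables
#'
#' Joins two [export_results()]-style tables (one per device) and computes,
#' per hand part: the per-device pooled SDs and the difference of means;
#' plus the Pearson correlation per measure family (unit), over
#' participant/part/repetition-matched pairs.
#'
#' @param results_a,results_b data.frames in the result layout.
#' @param sd_method see [pooled_sd()].
#' @return list with `per_part` (data.frame: hand_part, units, sd_a, sd_b,
#'   dm) and `pearson` (data.frame: units, r, n_pairs).
#' @export
agreement_report <- function(results_a, results_b,
                             sd_method = c("mean", "pooled")) {
  sd_method <- match.arg(sd_method)
  for (df in list(results_a, results_b)) {
    missing <- setdiff(RESULT_COLUMNS, names(df))
    if (length(missing) > 0) {
      stop("result table missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  parts <- intersect(unique(results_a$hand_part), unique(results_b$hand_part))
  if (length(parts) == 0) stop("no shared hand parts", call. = FALSE)
  per_part <- do.call(rbind, lapply(parts, function(part) {
    a <- results_a[results_a$hand_part == part, ]
    b <- results_b[results_b$hand_part == part, ]
    ua <- unique(a$units); ub <- unique(b$units)
    if (length(ua) != 1 || !identical(ua, ub)) {
      stop("unit mismatch for hand part '", part, "'", call. = FALSE)
    }
    data.frame(hand_part = part, units = ua,
               sd_a = pooled_sd(a$value, a$participant, sd_method),
               sd_b = pooled_sd(b$value, b$participant, sd_method),
               dm = difference_of_means(a$value, a$participant,
                                        b$value, b$participant))
  }))
  key <- function(df) paste(df$participant, df$hand_part, df$repetition)
  fam <- do.call(rbind, lapply(unique(per_part$units), function(u) {
    a <- results_a[results_a$units == u & results_a$hand_part %in% parts, ]
    b <- results_b[results_b$units == u & results_b$hand_part %in% parts, ]
    i <- match(key(a), key(b))
    ok <- !is.na(i)
    if (sum(ok) < 3) return(NULL)
    data.frame(units = u, r = pearson(a$value[ok], b$value[i[ok]]),
               n_pairs = sum(ok))
  }))
  list(per_part = per_part, pearson = fam)
}
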