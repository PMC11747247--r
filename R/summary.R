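#' Group-level accuracy by SOA condition and session
#'
#' Pools responses per SOA condition across all subliminal-target delays
#' within subject and session, then summarises across subjects: mean
#' accuracy, standard error of the mean (0 by convention when only one
#' subject contributes) and subject count, per session and condition. These
#' are the descriptive inputs one would hand to a standard two-way ANOVA;
#' no inferential statistics are computed here.
#'
#' @param trials trial table (see [generate_experiment()]).
#' @return Data frame with columns `session`, `soa_condition`,
#'   `mean_accuracy`, `sem`, `n`, ordered short to long SOA.
#' @export
accuracy_by_condition <- function(trials) {
  stopifnot(is.data.frame(trials))
  task <- trials[!is.na(trials$correct), , drop = FALSE]
  if (nrow(task) == 0) stop_invalid("no task (non-catch) trials")
  missing <- setdiff(soa_conditions(), unique(task$soa_condition))
  if (length(missing)) {
    warning("condition(s) absent and omitted: ",
            paste(missing, collapse = ", "))
  }
  per_subj <- stats::aggregate(
    correct ~ subject + session + soa_condition,
    data = task, FUN = mean
  )
  out <- do.call(rbind, lapply(
    split(per_subj, per_subj[c("session", "soa_condition")], drop = TRUE),
    function(g) {
      n <- nrow(g)
      data.frame(
        session = g$session[1],
        soa_condition = g$soa_condition[1],
        mean_accuracy = mean(g$correct),
        sem = if (n > 1) stats::sd(g$correct) / sqrt(n) else 0,
        n = n,
        stringsAsFactors = FALSE
      )
    }
  ))
  lev <- intersect(soa_conditions(), unique(out$soa_condition))
  out <- out[order(out$session, match(out$soa_condition, lev)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catch-trial "seen" rates
#'
#' Fraction of "yes" (seen) reports per subject, session and catch type.
#' Comparable real and fake rates indicate that the subliminal stimulus was
#' indeed below the perceptual threshold.
#'
#' @param trials trial table containing catch trials.
#' @return Data frame with columns `subject`, `session`, `catch_type`
#'   (`"real"`/`"fake"`), `seen_rate`, `n`.
#' @export
catch_rates <- function(trials) {
  stopifnot(is.data.frame(trials))
  ct <- trials[trials$soa_condition %in% c("catch_real", "catch_fake"), ,
               drop = FALSE]
  if (nrow(ct) == 0) stop_invalid("no catch trials present")
  ct$catch_type <- ifelse(ct$soa_condition == "catch_real", "real", "fake")
  agg_rate <- stats::aggregate(
    reported_seen ~ subject + session + catch_type,
    data = ct, FUN = mean
  )
  agg_n <- stats::aggregate(
    reported_seen ~ subject + session + catch_type,
    data = ct, FUN = length
  )
  out <- data.frame(
    subject = agg_rate$subject, session = agg_rate$session,
    catch_type = agg_rate$catch_type,
    seen_rate = agg_rate$reported_seen,
    n = agg_n$reported_seen,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject, out$session, out$catch_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
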