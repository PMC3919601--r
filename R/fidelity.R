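#' Recoding percentage from dual-luciferase readings
#'
#' Computes the recoding rate of a test reporter (frameshifting,
#' stop-codon readthrough or misreading construct) relative to an in-frame
#' control reporter: per-replicate firefly/renilla ratios are formed for
#' both reporters and the percentage is `100 * mean(r_test) /
#' mean(r_control)` (ratio of means -- replicates are independent cultures,
#' not paired; `method = "mean_of_ratios"` averages replicate-wise ratios
#' against the control mean instead, which is identical here but kept as an
#' explicit alternative convention).  The SEM is propagated to first order
#' from the two means' SEMs.
#'
#' @param test,control Tibbles with columns `firefly` and `renilla`
#'   (readings for the test and control reporters).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return An object of class `fidelity_result`: `percent`, `sem`, `n`,
#'   and `replicate_percent` (per-replicate recoding values used by
#'   [compare_strains()]).
#' @examples
#' ctl <- tibble::tibble(firefly = rep(50, 4), renilla = rep(100, 4))
#' tst <- tibble::tibble(firefly = rep(5, 4), renilla = rep(100, 4))
#' recoding_percent(tst, ctl)$percent # 10
#' @export
recoding_percent <- function(test, control,
                             method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  for (df in list(test, control)) {
    if (!all(c("firefly", "renilla") %in% names(df))) {
      abort("readings need columns firefly and renilla")
    }
    if (nrow(df) == 0) abort("reporter readings must be non-empty")
    if (any(df$renilla <= 0)) abort("renilla readings must be positive")
  }
  r_test <- test$firefly / test$renilla
  r_control <- control$firefly / control$renilla
  cv_control <- sd(r_control) / mean(r_control)
  if (is.finite(cv_control) && cv_control > 0.5) {
    warn("control reporter ratios have CV > 50%; normalization is unstable")
  }
  mt <- mean(r_test)
  mc <- mean(r_control)
  if (method == "ratio_of_means") {
    percent <- 100 * mt / mc
    replicate_percent <- 100 * r_test / mc
    sem_t <- sd(r_test) / sqrt(length(r_test))
    sem_c <- sd(r_control) / sqrt(length(r_control))
    sem <- if (length(r_test) >= 2 && length(r_control) >= 2) {
      percent * sqrt((sem_t / mt)^2 + (sem_c / mc)^2)
    } else {
      NA_real_
    }
  } else {
    # replicate-wise pairing of test against control cultures
    if (length(r_test) != length(r_control)) {
      abort("mean_of_ratios requires equal replicate counts")
    }
    replicate_percent <- 100 * r_test / r_control
    percent <- mean(replicate_percent)
    sem <- sd(replicate_percent) / sqrt(length(replicate_percent))
  }
  structure(list(percent = percent, sem = sem, n = length(r_test),
                 replicate_percent = replicate_percent, method = method),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("Recoding: %.3f%% (SEM %.3f, n = %d)\n",
              x$percent, x$sem, x$n))
  invisible(x)
}

#' Compare recoding between two strains
#'
#' Two-sample Student's t-test (pooled variance) on the per-replicate
#' recoding values of two [recoding_percent()] results; two-sided p-value.
#' Set `welch = TRUE` for the unequal-variance form.
#'
#' @param a,b `fidelity_result` objects (or bare numeric vectors of
#'   per-replicate values), each with at least 2 replicates.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return Tibble with `statistic` (t), `df` and `p_value`.
#' @export
compare_strains <- function(a, b, welch = FALSE) {
  va <- if (inherits(a, "fidelity_result")) a$replicate_percent else a
  vb <- if (inherits(b, "fidelity_result")) b$replicate_percent else b
  if (length(va) < 2 || length(vb) < 2) {
    abort("at least 2 replicates per group are required")
  }
  ht <- t.test(va, vb, var.equal = !welch)
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value)
}
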