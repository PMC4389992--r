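#' Assemble cause-specific survival records
#'
#' Cancer deaths are events; other-cause deaths, survivors and subjects with
#' unknown vital status are censored at their last-contact time. Records
#' with missing or non-positive follow-up, or missing AJCC stage, are
#' dropped with a message (their count is kept in attributes).
#'
#' @param clinical data.frame with \code{subject_id}, \code{vital_status},
#'   \code{follow_months}, \code{age}, \code{sex}, \code{stage},
#'   \code{tp53}, \code{kras}, \code{msi}, \code{cimp}.
#' @param tertiles named character/factor vector of DPES tertile labels
#'   ("T1"-"T3") per subject, e.g. one column of [dpesTertiles()] output.
#' @return data.frame with \code{time}, \code{event} (1 = cancer death,
#'   0 = censored), \code{dpes_tertile} and the adjustment covariates;
#'   attributes \code{n_dropped_time} and \code{n_dropped_stage}.
#' @export
buildSurvivalRecords <- function(clinical, tertiles) {
    need <- c("subject_id", "vital_status", "follow_months", "age", "sex",
              "stage", "tp53", "kras", "msi", "cimp")
    miss <- setdiff(need, colnames(clinical))
    if (length(miss))
        stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
    tert <- tertiles[match(clinical$subject_id, names(tertiles))]
    if (anyNA(tert))
        stop("tertile label missing for some subjects")

    badTime <- is.na(clinical$follow_months) | clinical$follow_months <= 0
    badStage <- is.na(clinical$stage)
    if (any(badTime))
        message(sprintf("dropping %d record(s) with missing/non-positive follow-up",
                        sum(badTime)))
    if (any(badStage & !badTime))
        message(sprintf("dropping %d record(s) with unknown stage",
                        sum(badStage & !badTime)))
    keep <- !badTime & !badStage

    out <- data.frame(
        subject_id = as.character(clinical$subject_id)[keep],
        time = as.numeric(clinical$follow_months)[keep],
        event = as.integer(clinical$vital_status == "crc_death")[keep],
        dpes_tertile = factor(as.character(tert)[keep],
                              levels = c("T1", "T2", "T3")),
        age = clinical$age[keep],
        sex = factor(clinical$sex[keep]),
        stage = factor(clinical$stage[keep], levels = sort(unique(clinical$stage))),
        tp53 = clinical$tp53[keep], kras = clinical$kras[keep],
        msi = clinical$msi[keep], cimp = clinical$cimp[keep],
        stringsAsFactors = FALSE)
    attr(out, "n_dropped_time") <- sum(badTime)
    attr(out, "n_dropped_stage") <- sum(badStage & !badTime)
    out
}

#' Cox proportional-hazards model of DPES tertiles on cancer mortality
#'
#' Fits a cause-specific Cox model with tertile indicators (T1 as referent)
#' adjusted for the requested covariates (age continuous; sex, stage as
#' factors; molecular phenotypes 0/1). Ties are handled with the Efron
#' approximation since monthly follow-up times guarantee ties. Returns
#' exponentiated Wald estimates and 95% CIs for T2 and T3 vs T1.
#'
#' @param records data.frame from [buildSurvivalRecords()] (any data.frame
#'   with \code{time}, \code{event}, \code{dpes_tertile} and the covariates
#'   works).
#' @param covariates adjustment covariates present in \code{records}
#'   (default: age, sex, stage and the four molecular phenotypes). Use
#'   \code{character()} for an unadjusted model.
#' @return data.frame with rows \code{T2} and \code{T3}: \code{hr},
#'   \code{lower}, \code{upper} (95% CI), \code{se_log_hr}, \code{p};
#'   attributes \code{n}, \code{n_events} and \code{separation} (TRUE when
#'   a tertile contrast looks numerically separated).
#' @export
fitCoxTertiles <- function(records,
                           covariates = c("age", "sex", "stage", "tp53",
                                          "kras", "msi", "cimp")) {
    if (sum(records$event) == 0L)
        stop("no events: cannot fit a Cox model")
    covariates <- intersect(covariates, colnames(records))
    drop <- vapply(records[covariates], function(x)
        length(unique(x)) < 2L, logical(1))
    covariates <- covariates[!drop]
    rhs <- paste(c("dpes_tertile", covariates), collapse = " + ")
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
    fit <- survival::coxph(fml, data = records, ties = "efron")
    if (!is.null(fit$info) || anyNA(stats::coef(fit)[c("dpes_tertileT2",
                                                       "dpes_tertileT3")]))
        stop("Cox model did not produce tertile estimates (check events per tertile)")
    sm <- summary(fit)
    rows <- c("dpes_tertileT2", "dpes_tertileT3")
    co <- sm$coefficients[rows, , drop = FALSE]
    ci <- sm$conf.int[rows, , drop = FALSE]
    out <- data.frame(
        term = c("T2", "T3"),
        hr = unname(co[, "exp(coef)"]),
        lower = unname(ci[, "lower .95"]),
        upper = unname(ci[, "upper .95"]),
        se_log_hr = unname(co[, "se(coef)"]),
        p = unname(co[, "Pr(>|z|)"]),
        stringsAsFactors = FALSE, row.names = c("T2", "T3"))
    attr(out, "n") <- sm$n
    attr(out, "n_events") <- sm$nevent
    attr(out, "separation") <- any(abs(co[, "coef"]) > 10)
    if (attr(out, "separation"))
        warning("tertile coefficient magnitude > 10: possible separation")
    out
}

#' Kaplan-Meier curves by DPES tertile
#'
#' Product-limit survival estimates per tertile, optionally written as a
#' plot file. Empty tertiles are omitted with a warning.
#'
#' @param records data.frame with \code{time}, \code{event},
#'   \code{dpes_tertile}.
#' @param file optional path for a PNG of the curves.
#' @return a \code{survival::survfit} object.
#' @export
kmByTertile <- function(records, file = NULL) {
    present <- table(records$dpes_tertile)
    if (any(present == 0L))
        warning("empty tertile(s) omitted: ",
                paste(names(present)[present == 0L], collapse = ", "))
    fit <- survival::survfit(
        survival::Surv(time, event) ~ dpes_tertile,
        data = droplevels(records))
    if (!is.null(file)) {
        grDevices::png(file, width = 720, height = 540)
        on.exit(grDevices::dev.off(), add = TRUE)
        graphics::plot(fit, col = seq_len(max(1L, length(fit$strata))),
                       lwd = 2, xlab = "Months from diagnosis",
                       ylab = "Cancer-specific survival")
        if (!is.null(fit$strata))
            graphics::legend("bottomleft", legend = names(fit$strata),
                             col = seq_along(fit$strata), lwd = 2, bty = "n")
    }
    fit
}

#' DPES summaries by AJCC stage
#'
#' Per-stage mean and SD of one pathway's DPES values plus a Welch
#' two-sample t-test comparing stages 1 and 4.
#'
#' @param scores numeric vector of DPES values per subject.
#' @param stage integer/factor vector of AJCC stages 1-4, aligned with
#'   \code{scores}.
#' @return one-row data.frame with \code{mean_1}..\code{mean_4},
#'   \code{sd_1}..\code{sd_4}, \code{n_1}..\code{n_4} and \code{p_1v4}.
#' @export
stageSummary <- function(scores, stage) {
    if (length(scores) != length(stage))
        stop("scores and stage must be aligned")
    stage <- as.integer(as.character(stage))
    keep <- !is.na(scores) & !is.na(stage)
    scores <- scores[keep]; stage <- stage[keep]
    s1 <- scores[stage == 1L]; s4 <- scores[stage == 4L]
    if (length(s1) < 2L || length(s4) < 2L)
        stop("need at least 2 subjects in each of stages 1 and 4")
    out <- as.data.frame(as.list(c(
        stats::setNames(vapply(1:4, function(s)
            mean(scores[stage == s]), numeric(1)), paste0("mean_", 1:4)),
        stats::setNames(vapply(1:4, function(s)
            stats::sd(scores[stage == s]), numeric(1)), paste0("sd_", 1:4)),
        stats::setNames(vapply(1:4, function(s)
            sum(stage == s), numeric(1)), paste0("n_", 1:4)))))
    out$p_1v4 <- if (stats::sd(s1) == 0 && stats::sd(s4) == 0 &&
                     mean(s1) == mean(s4)) 1 else
        stats::t.test(s1, s4, var.equal = FALSE)$p.value
    out
}
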