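#' Percent root-mean-square difference (PRD)
#'
#' `100 * sqrt(sum((ref - test)^2) / sum(ref^2))` between two equally
#' sampled amplitude series; only signals on the same grid are comparable.
#' The per-section variant restricts both sums to a wave span.
#'
#' @param ref,test numeric vectors of equal length
#' @param section optional `c(from, to)` index range restricting the sums
#' @return percentage
#' @export
prd <- function(ref, test, section = NULL) {
  if (length(ref) != length(test))
    stop("PRD requires signals sampled on the same grid")
  if (!is.null(section)) {
    idx <- seq(max(1, section[1]), min(length(ref), section[2]))
    ref <- ref[idx]; test <- test[idx]
  }
  e_ref <- sum(as.numeric(ref)^2)
  if (e_ref == 0) stop("reference signal has zero energy")
  100 * sqrt(sum((as.numeric(ref) - as.numeric(test))^2) / e_ref)
}

#' PRD of a record pair, whole and per wave section
#'
#' @param ref,test [uniform_signal()]s on the same grid
#' @param borders optional [borders_table()] with the wave spans
#' @param lead lead index
#' @return named list: `total` and, when borders are given, mean per-beat
#'   `p`, `qrs`, `t` section PRDs
#' @export
prd_sections <- function(ref, test, borders = NULL, lead = 1) {
  a <- ref$values[[lead]]
  n <- min(length(a), length(test$values[[lead]]))
  b <- test$values[[lead]][seq_len(n)]; a <- a[seq_len(n)]
  out <- list(total = prd(a, b))
  if (!is.null(borders)) {
    t_grid <- uniform_times(ref)[seq_len(n)]
    span_prd <- function(from, to) {
      vals <- mapply(function(f, t) {
        if (is.na(f) || is.na(t)) return(NA_real_)
        idx <- which(t_grid >= f & t_grid <= t)
        if (length(idx) < 2 || sum(as.numeric(a[idx])^2) == 0) return(NA_real_)
        prd(a[idx], b[idx])
      }, from, to)
      mean(vals, na.rm = TRUE)
    }
    out$p <- span_prd(borders$p_on, borders$p_end)
    out$qrs <- span_prd(borders$qrs_on, borders$qrs_end)
    out$t <- span_prd(borders$qrs_end, borders$t_end)
  }
  out
}

#' Beat detection statistics (Se, PPV, Fd)
#'
#' Greedy nearest-first one-to-one matching of predicted and reference beat
#' times within the tolerance (ties break toward the earlier reference
#' beat); unmatched references are false negatives, unmatched predictions
#' false positives.
#'
#' @param pred detected beat times (ms, sorted)
#' @param truth reference beat times (ms, sorted)
#' @param tol matching tolerance in ms
#' @return object of class `detection_stats`: counts `TP`, `FP`, `FN` and
#'   percentages `Se`, `PPV`, `Fd`
#' @export
detection_stats <- function(pred, truth, tol = 25.6) {
  pred <- sort(pred); truth <- sort(truth)
  used <- rep(FALSE, length(truth))
  tp <- 0L
  if (length(pred) && length(truth)) {
    pairs <- expand.grid(p = seq_along(pred), t = seq_along(truth))
    pairs$d <- abs(pred[pairs$p] - truth[pairs$t])
    pairs <- pairs[pairs$d <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$t), , drop = FALSE]
    used_p <- rep(FALSE, length(pred))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$p[r]; j <- pairs$t[r]
      if (!used_p[i] && !used[j]) {
        used_p[i] <- TRUE; used[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  fp <- length(pred) - tp
  fn <- length(truth) - tp
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  fd <- if (tp + fp + fn > 0) 100 * (fp + fn) / (tp + fp + fn) else NA_real_
  structure(list(TP = tp, FP = fp, FN = fn, Se = se, PPV = ppv, Fd = fd),
            class = "detection_stats")
}

#' @export
print.detection_stats <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  Se=%.4f%% PPV=%.4f%% Fd=%.4f%%\n",
              x$TP, x$FP, x$FN, x$Se, x$PPV, x$Fd))
  invisible(x)
}

#' Map an MITDB beat label to its AAMI class
#'
#' The standard five-class projection of the 14 handled MITDB beat types:
#' `{N,L,R} -> N`, `{A,j,x,a,J,e} -> S`, `{V,!,E} -> V`, `{F} -> F`,
#' `{Q} -> Q`.
#'
#' @param label character vector of MITDB labels
#' @return character vector of AAMI classes
#' @export
map_mitdb_to_aami <- function(label) {
  lut <- c(N = "N", L = "N", R = "N",
           A = "S", j = "S", x = "S", a = "S", J = "S", e = "S",
           V = "V", `!` = "V", E = "V",
           F = "F", Q = "Q")
  out <- lut[as.character(label)]
  if (anyNA(out))
    stop("unknown MITDB label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Confusion matrix and accuracy of a beat classification
#'
#' Clusters are mapped to reference labels by the majority label of their
#' members; the confusion matrix counts reference label (rows) against the
#' label of the assigned cluster (columns); accuracy is the diagonal share.
#'
#' @param assignments cluster indices per beat (`NA` ignored)
#' @param labels reference labels per beat
#' @param label_space label set ordering the matrix (defaults to observed)
#' @return list: `matrix`, `accuracy` (percent), `cluster_labels`
#' @export
confusion_stats <- function(assignments, labels, label_space = NULL) {
  stopifnot(length(assignments) == length(labels))
  ok <- !is.na(assignments)
  if (!any(ok)) stop("no classified beats")
  assignments <- assignments[ok]; labels <- as.character(labels[ok])
  if (is.null(label_space)) label_space <- sort(unique(labels))
  cl_label <- vapply(split(labels, assignments), function(ll)
    names(sort(table(ll), decreasing = TRUE))[1], "")
  pred <- cl_label[as.character(assignments)]
  m <- table(factor(labels, levels = label_space),
             factor(pred, levels = label_space))
  list(matrix = m, accuracy = 100 * sum(diag(m)) / sum(m),
       cluster_labels = cl_label)
}

# printed order of the 18 diagnostic features
wdd_feature_names <- c(
  "RR_int", "QRS_dur", "QT_int", "QTp_int", "P_dur", "PR_int",
  "QRS_peaks_no", "Q_wave_exist", "D_wave_exist", "T_shape", "P_shape",
  "ST_shape", "QRSp_amp", "QRSn_amp", "P_amp", "T_amp", "ST_elevation",
  "ST_slope")

wdd_weights <- c(2.5, 2.5, 1, 1, 2, 2, 1, 0.5, 0.1, 1.5, 1, 3,
                 1.5, 1.5, 1, 1, 3, 3)

wdd_categorical <- c(rep(FALSE, 6), TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     rep(FALSE, 6))

#' Extract the 18 diagnostic features of one beat
#'
#' Interval features come from the wave borders, amplitude features from
#' signal extrema within the wave spans (in uV), ST features from the
#' window after QRS end against the PR baseline.  Shape features are
#' categorical: wave polarity for P and T (`absent`, `pos`, `neg`,
#' `biphasic`), slope class for ST (`horizontal`, `up`, `down`).  Features
#' whose borders are missing are `NA` and drop out of the WDD with weight
#' renormalization.
#'
#' @param nu an [nu_signal()] (a pseudo-non-uniform record works equally)
#' @param lead lead index
#' @param fiducial the beat detection point (ms)
#' @param borders the beat's [wave_borders()] (absolute ms)
#' @param rr_prev preceding RR interval (ms)
#' @return named list of 18 features (class `wdd_features`)
#' @export
extract_wdd_features <- function(nu, lead = 1, fiducial, borders,
                                 rr_prev = NA_real_) {
  ts <- nu$times
  v <- as.numeric(nu$values[[lead]]) * nu$gain
  span <- function(from, to) {
    if (is.na(from) || is.na(to)) return(numeric(0))
    v[ts >= from & ts <= to]
  }
  qrs <- span(borders$qrs_on, borders$qrs_end)
  pw <- span(borders$p_on, borders$p_end)
  # baseline: the PR segment (or the span just before QRS onset)
  base_span <- if (!is.na(borders$p_end)) span(borders$p_end, borders$qrs_on)
               else span(borders$qrs_on - 40, borders$qrs_on)
  baseline <- if (length(base_span)) stats::median(base_span) else 0
  st_t <- ts[ts >= borders$qrs_end + 20 & ts <= borders$qrs_end + 80]
  st_v <- v[ts >= borders$qrs_end + 20 & ts <= borders$qrs_end + 80]
  tw <- span(borders$qrs_end, borders$t_end)
  t_peak_t <- if (length(tw)) {
    tt <- ts[ts >= borders$qrs_end & ts <= borders$t_end]
    tt[which.max(abs(tw - baseline))]
  } else NA_real_
  shape_of <- function(w) {
    if (!length(w)) return("absent")
    dev <- w - baseline
    hi <- max(dev); lo <- min(dev)
    thr <- 0.25 * max(abs(dev))
    if (hi > thr && lo < -thr) "biphasic" else if (hi >= -lo) "pos" else "neg"
  }
  n_peaks <- if (length(qrs) >= 3) {
    dev <- qrs - baseline
    ex <- series_extrema(dev)
    sum(abs(dev[ex]) > 0.1 * max(abs(dev)))
  } else NA_real_
  q_exists <- if (length(qrs)) {
    qt <- ts[ts >= borders$qrs_on & ts <= borders$qrs_end]
    r_at <- qt[which.max(abs(qrs - baseline))]
    pre <- qrs[qt < r_at]
    length(pre) > 0 && min(pre - baseline) < -0.05 * max(abs(qrs - baseline))
  } else NA
  d_exists <- FALSE # delta waves are not modelled by the generator
  st_slope <- if (length(st_v) >= 2)
    stats::coef(stats::lm(st_v ~ st_t))[[2]] else NA_real_
  st_elev <- if (length(st_v)) mean(st_v) - baseline else NA_real_
  f <- list(
    RR_int = rr_prev,
    QRS_dur = borders$qrs_end - borders$qrs_on,
    QT_int = if (is.na(borders$t_end)) NA_real_ else borders$t_end - borders$qrs_on,
    QTp_int = if (is.na(t_peak_t)) NA_real_ else t_peak_t - borders$qrs_on,
    P_dur = if (is.na(borders$p_on)) NA_real_ else borders$p_end - borders$p_on,
    PR_int = if (is.na(borders$p_on)) NA_real_ else borders$qrs_on - borders$p_on,
    QRS_peaks_no = n_peaks,
    Q_wave_exist = q_exists,
    D_wave_exist = d_exists,
    T_shape = shape_of(tw),
    P_shape = shape_of(pw),
    ST_shape = if (is.na(st_slope)) NA_character_
               else if (st_slope > 0.5) "up" else if (st_slope < -0.5) "down"
               else "horizontal",
    QRSp_amp = if (length(qrs)) max(qrs - baseline) else NA_real_,
    QRSn_amp = if (length(qrs)) min(qrs - baseline) else NA_real_,
    P_amp = if (length(pw)) {
      dev <- pw - baseline; dev[which.max(abs(dev))]
    } else NA_real_,
    T_amp = if (length(tw)) {
      dev <- tw - baseline; dev[which.max(abs(dev))]
    } else NA_real_,
    ST_elevation = st_elev,
    ST_slope = st_slope)
  structure(f[wdd_feature_names], class = "wdd_features")
}

#' Weighted diagnostic distortion (WDD)
#'
#' `WDD = 100 * (dB' L dB) / tr(L)` where `dB` is the normalized feature
#' difference vector and `L` the printed diagonal weight matrix
#' `diag[2.5 2.5 1 1 2 2 1 0.5 0.1 1.5 1 3 1.5 1.5 1 1 3 3]`.  Numeric
#' components use the clipped relative difference
#' `|b - b'| / max(|b|, |b'|)`; categorical components are 0/1 mismatches.
#' Features missing on either side are dropped with weight renormalization.
#'
#' @param beta,beta_hat two `wdd_features` vectors ([extract_wdd_features()])
#' @return percentage in `[0, 100]`
#' @export
wdd <- function(beta, beta_hat) {
  db <- numeric(length(wdd_feature_names))
  avail <- logical(length(db))
  for (i in seq_along(wdd_feature_names)) {
    a <- beta[[wdd_feature_names[i]]]
    b <- beta_hat[[wdd_feature_names[i]]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) next
    avail[i] <- TRUE
    db[i] <- if (wdd_categorical[i]) {
      as.numeric(!identical(as.character(a), as.character(b)))
    } else {
      den <- max(abs(a), abs(b))
      if (den == 0) 0 else min(abs(a - b) / den, 1)
    }
  }
  if (!any(avail)) stop("no commonly available features")
  w <- wdd_weights[avail]
  100 * sum(w * db[avail]^2) / sum(w)
}

#' Four-variant cross-check of the interpretation chain
#'
#' Builds the four signal variants of the evaluation scheme from one
#' uniform record -- oECG (the original), pECG (the original in `{t, v}`
#' form), nECG (arbitrarily sampled along the wave-border-anchored model)
#' and uECG (nECG projected back to the uniform grid) -- runs detection,
#' delineation and feature extraction on each, and reports PRD between oECG
#' and uECG (whole and per section), the five pairwise WDD columns, and
#' per-variant detection statistics.
#'
#' @param record a [uniform_signal()]
#' @param truth_beats reference beat times (ms)
#' @param truth_borders a [borders_table()] driving the sampling model
#' @param profile an [slb_profile()]
#' @param det_config,delin_config stage configurations
#' @return list: `prd` (list total/p/qrs/t), `wdd` (named columns
#'   `oECG_uECG`, `pECG_nECG`, `uECG_nECG`, `oECG_pECG`, `nECG_oECG`),
#'   `detection` (per-variant [detection_stats()]), `borders` (per-variant
#'   tables), `compression_ratio`
#' @export
cross_check <- function(record, truth_beats, truth_borders,
                        profile = slb_profile(),
                        det_config = detector_config(),
                        delin_config = delineator_config()) {
  n <- length(truth_beats)
  slbs <- lapply(seq_len(n), function(k) {
    b <- truth_borders[k, ]
    wb <- tryCatch(
      wave_borders(qrs_on = b$qrs_on, qrs_end = b$qrs_end, p_on = b$p_on,
                   p_end = b$p_end, t_end = b$t_end),
      error = function(e) NULL)
    if (is.null(wb)) return(NULL)
    rr <- c(if (k > 1) truth_beats[k - 1] else truth_beats[k] - 750,
            truth_beats[k],
            if (k < n) truth_beats[k + 1] else truth_beats[k] + 750)
    project_slb(profile, wb, rr)
  })
  pECG <- as_pseudo_nonuniform(record)
  nECG <- sample_nonuniform(record, slbs)
  uECG <- uniformize(nECG, record$fs)
  variants <- list(oECG = pECG, pECG = pECG, nECG = nECG,
                   uECG = as_pseudo_nonuniform(uECG))
  run <- function(nu) {
    det <- detect_beats(nu, det_config)
    tab <- delineate_record(nu, det, config = delin_config)
    feats <- lapply(seq_along(det), function(k) {
      b <- tab[k, ]
      wb <- tryCatch(
        wave_borders(qrs_on = b$qrs_on, qrs_end = b$qrs_end, p_on = b$p_on,
                     p_end = b$p_end, t_end = b$t_end),
        error = function(e) NULL)
      if (is.null(wb)) return(NULL)
      rrp <- if (k > 1) det[k] - det[k - 1] else NA_real_
      extract_wdd_features(nu, 1, det[k], wb, rr_prev = rrp)
    })
    list(det = det, borders = tab, feats = feats)
  }
  res <- lapply(variants, run)
  # mean WDD over beats matched between two variants
  pair_wdd <- function(a, b) {
    if (!length(res[[a]]$det) || !length(res[[b]]$det)) return(NA_real_)
    vals <- c()
    for (k in seq_along(res[[a]]$det)) {
      j <- which.min(abs(res[[b]]$det - res[[a]]$det[k]))
      if (abs(res[[b]]$det[j] - res[[a]]$det[k]) > 25.6) next
      fa <- res[[a]]$feats[[k]]; fb <- res[[b]]$feats[[j]]
      if (is.null(fa) || is.null(fb)) next
      vals <- c(vals, wdd(fa, fb))
    }
    if (length(vals)) mean(vals) else NA_real_
  }
  list(
    prd = prd_sections(record, uECG, truth_borders),
    wdd = list(oECG_uECG = pair_wdd("oECG", "uECG"),
               pECG_nECG = pair_wdd("pECG", "nECG"),
               uECG_nECG = pair_wdd("uECG", "nECG"),
               oECG_pECG = pair_wdd("oECG", "pECG"),
               nECG_oECG = pair_wdd("nECG", "oECG")),
    detection = lapply(res, function(r) detection_stats(r$det, truth_beats)),
    borders = lapply(res, `[[`, "borders"),
    compression_ratio = compression_ratio(record, nECG))
}
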