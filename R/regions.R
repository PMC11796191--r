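# Euclidean distance (in pixels) of every pixel to the nearest TRUE pixel
dist_to_mask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  as.matrix(EBImage::distmap((!mask) * 1, metric = "euclidean"))
}

#' Partition tissue into tumour, adipose and stroma regions
#'
#' Tumour and adipose segmentations (components smaller than
#' `min_region_px`, default 1000 px or about 250 um^2, are excluded first as
#' likely artefacts or singular cells) are each dilated by a total of
#' `dilation_um` (default 150 um) — but grown alternately in small
#' increments, each increment forbidden from claiming the other's pixels, so
#' the two regions meet without overlap near the equidistant front. Growth
#' claims any non-background tissue pixel. The remaining tissue is the
#' stroma region, which by definition includes the lymphocyte clusters.
#'
#' @param lm A post-processed [label_map()].
#' @param dilation_um Total dilation in microns.
#' @param step_um Increment per alternation; must be in (0, dilation_um].
#' @param min_region_px Minimum seed component size (strict).
#' @return List of class `region_partition`: logical masks `tumour`,
#'   `adipose`, `stroma` (pairwise disjoint, union = tissue extent), plus
#'   `pixel_size_um`.
#' @export
partition_regions <- function(lm, dilation_um = 150, step_um = 5,
                              min_region_px = 1000) {
  stopifnot(inherits(lm, "label_map"))
  if (step_um <= 0 || step_um > dilation_um) {
    stop("step_um must be in (0, dilation_um]")
  }
  ps <- lm$pixel_size_um
  tissue <- lm$labels != class_code("BACKGROUND")
  seed_of <- function(cls) {
    comp <- cpp_label_components(lm$labels == class_code(cls), 8L)
    n <- max(comp)
    if (n == 0) return(comp > 0)
    sizes <- tabulate(comp, n)
    matrix(comp %in% which(sizes >= min_region_px), nrow(comp))
  }
  tum <- seed_of("TUMOUR")
  adi <- seed_of("ADIPOSE")
  step_px <- max(1, round(step_um / ps))
  n_steps <- ceiling(dilation_um / step_um)
  for (k in seq_len(n_steps)) {
    if (any(tum)) {
      d <- dist_to_mask(tum)
      tum <- tum | (d <= step_px & tissue & !adi)
    }
    if (any(adi)) {
      d <- dist_to_mask(adi)
      adi <- adi | (d <= step_px & tissue & !tum)
    }
  }
  structure(list(tumour = tum & tissue, adipose = adi & tissue,
                 stroma = tissue & !tum & !adi,
                 pixel_size_um = ps, dilation_um = dilation_um),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> tumour %d px, adipose %d px, stroma %d px (dilation %g um)\n",
              sum(x$tumour), sum(x$adipose), sum(x$stroma), x$dilation_um))
  invisible(x)
}

#' Concentric distance rings around a seed mask
#'
#' Ring k holds the pixels at Euclidean distance ((k-1)w, kw] microns from
#' the seed, clipped to the tissue extent; the seed itself (distance 0) is
#' in no ring, so rings around the vasculature are measured on non-vessel
#' tissue.
#'
#' @param seed_mask Logical matrix (non-empty).
#' @param lm The [label_map()] providing the tissue extent and pixel size.
#' @param ring_width_um Ring width in microns (default 25).
#' @param n_rings Number of rings.
#' @param exclude Optional logical matrix of pixels to drop from every ring.
#' @return List of class `ring_set`: `rings` (list of disjoint logical
#'   masks ordered by distance), `ring_width_um`, `n_rings`.
#' @export
distance_rings <- function(seed_mask, lm, ring_width_um = 25, n_rings = 8,
                           exclude = NULL) {
  stopifnot(inherits(lm, "label_map"))
  if (!any(seed_mask)) stop("seed mask is empty")
  ps <- lm$pixel_size_um
  w_px <- ring_width_um / ps
  d <- dist_to_mask(seed_mask)
  tissue <- lm$labels != class_code("BACKGROUND")
  rings <- purrr::map(seq_len(n_rings), function(k) {
    m <- d > (k - 1) * w_px & d <= k * w_px & tissue
    if (!is.null(exclude)) m <- m & !exclude
    m
  })
  structure(list(rings = rings, ring_width_um = ring_width_um,
                 n_rings = n_rings), class = "ring_set")
}

#' Lymphocyte percentage within a mask
#'
#' Lymphocyte area relative to the combined stroma and lymphocyte area,
#' in percent. Missing when the mask holds no stromal compartment.
#'
#' @param mask Logical matrix.
#' @param lm A [label_map()].
#' @return Percentage in \[0, 100\] or `NA`.
#' @export
lymphocyte_percentage <- function(mask, lm) {
  stopifnot(inherits(lm, "label_map"))
  ly <- sum((lm$labels == class_code("LYMPHOCYTE")) & mask)
  st <- sum((lm$labels %in% class_code(c("STROMA", "LYMPHOCYTE"))) & mask)
  if (st == 0) return(NA_real_)
  100 * ly / st
}

#' Lymphocyte percentage profile over distance rings
#'
#' @param rings A [distance_rings()] result.
#' @param lm The [label_map()].
#' @return Tibble: `ring`, `distance_lo_um`, `distance_hi_um`,
#'   `lymphocyte_pct`.
#' @export
lymphocytes_by_distance <- function(rings, lm) {
  w <- rings$ring_width_um
  purrr::imap(rings$rings, function(m, k) {
    tibble::tibble(ring = k, distance_lo_um = (k - 1) * w,
                   distance_hi_um = k * w,
                   lymphocyte_pct = lymphocyte_percentage(m, lm))
  }) |> purrr::list_rbind()
}

#' Vessel density and size per distance ring
#'
#' Applies the stromal density and mean-area measures ring by ring; empty
#' rings yield missing values.
#'
#' @param vessels Tibble from [measure_vessels()].
#' @param rings A [distance_rings()] result.
#' @param lm The [label_map()].
#' @return Tibble: `ring`, `distance_lo_um`, `distance_hi_um`, `n_vessels`,
#'   `density_per_mm2`, `mean_area_um2`.
#' @export
vessels_by_distance <- function(vessels, rings, lm) {
  w <- rings$ring_width_um
  purrr::imap(rings$rings, function(m, k) {
    vr <- vessels_in_region(vessels, m)
    dens <- if (any(m)) measure_density(vessels, m, lm) else NA_real_
    tibble::tibble(ring = k, distance_lo_um = (k - 1) * w,
                   distance_hi_um = k * w, n_vessels = nrow(vr),
                   density_per_mm2 = dens,
                   mean_area_um2 = if (nrow(vr)) mean(vr$area_um2) else NA_real_)
  }) |> purrr::list_rbind()
}

#' Tissue composition metrics within the tumour region
#'
#' The tumour-stroma ratio (tumour area over combined stroma and lymphocyte
#' area inside the tumour region) and the tumour-infiltrating-lymphocyte
#' percentage (lymphocyte share of that stromal compartment), plus the
#' overall lymphocyte percentage of the whole tissue.
#'
#' @param partition A [partition_regions()] result.
#' @param lm The [label_map()].
#' @return One-row tibble: `lymphocyte_pct`, `tumour_stroma_ratio`,
#'   `til_pct`.
#' @export
composition <- function(partition, lm) {
  stopifnot(inherits(partition, "region_partition"), inherits(lm, "label_map"))
  tmask <- partition$tumour
  tum_px <- sum((lm$labels == class_code("TUMOUR")) & tmask)
  str_px <- sum((lm$labels %in% class_code(c("STROMA", "LYMPHOCYTE"))) & tmask)
  tissue <- lm$labels != class_code("BACKGROUND")
  tibble::tibble(
    lymphocyte_pct = lymphocyte_percentage(tissue, lm),
    tumour_stroma_ratio = if (str_px > 0) tum_px / str_px else NA_real_,
    til_pct = lymphocyte_percentage(tmask, lm))
}

#' Two-tailed t-tests between groups with optional BH correction
#'
#' With two group levels a single two-sample (or paired) t-test is run; with
#' more levels, consecutive levels are compared pairwise — the design used
#' for distance-ring profiles, where each subject contributes one value per
#' ring and consecutive rings are compared with paired tests. P-values are
#' adjusted with the Benjamini-Hochberg step-up procedure when `adjust` is
#' set.
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names) of the measured
#'   value and the grouping variable.
#' @param subject Column name identifying the pairing unit (required for
#'   `paired = TRUE`).
#' @param paired Use paired t-tests.
#' @param adjust Apply Benjamini-Hochberg correction across the comparisons.
#' @return Tibble: `group1`, `group2`, `n1`, `n2`, `estimate`, `statistic`,
#'   `df`, `p_value`, `p_adjusted`. Comparisons with fewer than two
#'   observations per group are reported missing with a warning.
#' @export
compare_groups <- function(data, value, group, subject = NULL,
                           paired = FALSE, adjust = TRUE) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  subject_q <- rlang::enquo(subject)
  subject <- if (rlang::quo_is_null(subject_q)) NULL
             else rlang::as_name(rlang::quo_get_expr(subject_q))
  g <- data[[group]]
  lev <- if (is.factor(g)) levels(g) else sort(unique(g))
  if (length(lev) < 2) stop("need at least two group levels")
  pairs <- if (length(lev) == 2) list(lev) else
    purrr::map(seq_len(length(lev) - 1), ~ lev[c(.x, .x + 1)])
  rows <- purrr::map(pairs, function(pr) {
    d1 <- data[g == pr[1], , drop = FALSE]
    d2 <- data[g == pr[2], , drop = FALSE]
    if (paired) {
      if (is.null(subject)) stop("paired tests need a subject column")
      m <- dplyr::inner_join(d1[, c(subject, value)], d2[, c(subject, value)],
                             by = subject, suffix = c("_1", "_2"))
      m <- m[stats::complete.cases(m), , drop = FALSE]
      x <- m[[paste0(value, "_1")]]; y <- m[[paste0(value, "_2")]]
      n1 <- n2 <- nrow(m)
      ok <- n1 >= 2 && sd(x - y) > 0
      tt <- if (ok) t.test(x, y, paired = TRUE) else NULL
    } else {
      x <- d1[[value]][!is.na(d1[[value]])]
      y <- d2[[value]][!is.na(d2[[value]])]
      n1 <- length(x); n2 <- length(y)
      ok <- n1 >= 2 && n2 >= 2
      tt <- if (ok) t.test(x, y) else NULL
    }
    if (is.null(tt)) {
      warning(sprintf("insufficient observations for %s vs %s", pr[1], pr[2]))
      return(tibble::tibble(group1 = as.character(pr[1]),
                            group2 = as.character(pr[2]),
                            n1 = n1, n2 = n2, estimate = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    }
    tibble::tibble(group1 = as.character(pr[1]), group2 = as.character(pr[2]),
                   n1 = n1, n2 = n2,
                   estimate = unname(if (paired) tt$estimate
                                     else diff(rev(tt$estimate))),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  })
  out <- purrr::list_rbind(rows)
  out$p_adjusted <- if (adjust) p.adjust(out$p_value, method = "BH")
                    else out$p_value
  out
}

#' Pearson correlation of predicted vs ground-truth vascular parameters
#'
#' For each shared numeric parameter column, the Pearson correlation between
#' measurements from the predicted and the ground-truth segmentations, with
#' two-tailed p-values.
#'
#' @param pred_params,true_params Data frames with matching rows (one per
#'   image or region) and identical numeric parameter columns.
#' @return Tibble: `parameter`, `n`, `r`, `p_value`. Parameters with zero
#'   variance or fewer than 3 pairs are reported missing.
#' @export
correlate_parameters <- function(pred_params, true_params) {
  cols <- intersect(names(pred_params), names(true_params))
  cols <- cols[vapply(pred_params[cols], is.numeric, logical(1))]
  if (!length(cols)) stop("no shared numeric parameter columns")
  purrr::map(cols, function(cl) {
    x <- pred_params[[cl]]; y <- true_params[[cl]]
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(parameter = cl, n = n, r = NA_real_,
                            p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(parameter = cl, n = n, r = unname(ct$estimate),
                   p_value = ct$p.value)
  }) |> purrr::list_rbind()
}
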