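#' Tissue classes of the CD-31 segmentation model
#'
#' The segmentation operates over ten tissue classes: vessels, vascular smooth
#' muscle, tumour regions, benign epithelial cells, adipose, lymphocyte
#' clusters, CD-31 positive leukocytes, nerves, stroma and slide background.
#' Every pixel of a label map carries exactly one of these integer codes.
#' Tissue that is not covered by any annotation is classified as stroma.
#'
#' @return A tibble with columns `code` (integer 1-10) and `name`.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  tibble::tibble(
    code = 1:10,
    name = c("VESSEL", "MUSCLE", "TUMOUR", "BENIGN", "ADIPOSE",
             "LYMPHOCYTE", "LEUKOCYTE", "NERVE", "STROMA", "BACKGROUND")
  )
}

#' Integer code of a tissue class
#'
#' @param name Class name, one of the ten names in [tissue_classes()].
#' @return Integer code.
#' @export
class_code <- function(name) {
  tc <- tissue_classes()
  i <- match(toupper(name), tc$name)
  if (anyNA(i)) stop("unknown tissue class: ", paste(name[is.na(i)], collapse = ", "))
  tc$code[i]
}

#' Default per-class loss weights
#'
#' Class weights reflect prevalence and importance: vessels carry the highest
#' weight (10) because vessel segmentation quality dominates all downstream
#' morphometry; the rare CD-31 positive leukocytes and nerves get 5; tumour,
#' benign epithelium, lymphocytes and smooth muscle get 2; the prevalent
#' adipose, stroma and background classes get 1 (sum 31).
#'
#' @return Named numeric vector of length 10 ordered by class code.
#' @export
#' @examples
#' sum(default_class_weights())  # 31
default_class_weights <- function() {
  w <- c(VESSEL = 10, MUSCLE = 2, TUMOUR = 2, BENIGN = 2, ADIPOSE = 1,
         LYMPHOCYTE = 2, LEUKOCYTE = 5, NERVE = 5, STROMA = 1, BACKGROUND = 1)
  w[tissue_classes()$name]
}

#' Construct a label map
#'
#' A label map is an integer matrix of tissue-class codes together with the
#' physical pixel size. The matrix is indexed `[row, col]` with origin at the
#' top-left; one pixel covers `pixel_size_um^2` square microns.
#'
#' @param labels Integer matrix of class codes in 1..10.
#' @param pixel_size_um Edge length of one pixel in microns (> 0). The
#'   acquisition default of 20x scans used throughout is 0.5034.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size_um = 0.5034) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  storage.mode(labels) <- "integer"
  bad <- labels < 1L | labels > 10L
  if (any(bad, na.rm = TRUE) || anyNA(labels)) {
    stop("label map contains codes outside 1..10")
  }
  structure(list(labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d px, pixel size %.4f um\n", d[1], d[2], x$pixel_size_um))
  tab <- tabulate(x$labels, nbins = 10L)
  nm <- tissue_classes()$name
  present <- tab > 0
  cat("  ", paste(sprintf("%s:%d", nm[present], tab[present]), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' Per-class pixel counts of a label map
#'
#' @param lm A [label_map()].
#' @return Tibble with `code`, `name`, `n_px`, `area_um2`.
#' @export
class_counts <- function(lm) {
  stopifnot(inherits(lm, "label_map"))
  tc <- tissue_classes()
  tc$n_px <- tabulate(lm$labels, nbins = 10L)
  tc$area_um2 <- tc$n_px * lm$pixel_size_um^2
  tc
}

#' One-hot expansion of a label map
#'
#' @param lm A [label_map()] or integer matrix.
#' @param n_classes Number of classes (default 10).
#' @return Array `[rows, cols, n_classes]` of 0/1, per-pixel sums all 1.
#' @export
one_hot <- function(lm, n_classes = 10L) {
  labels <- if (inherits(lm, "label_map")) lm$labels else lm
  stopifnot(is.matrix(labels))
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], n_classes))
  idx <- cbind(rep.int(seq_len(d[1]), d[2]),
               rep(seq_len(d[2]), each = d[1]),
               as.vector(labels))
  out[idx] <- 1
  out
}

# internal: binary mask of a set of classes
class_mask <- function(lm, classes) {
  labels <- if (inherits(lm, "label_map")) lm$labels else lm
  matrix(labels %in% as.integer(classes), nrow(labels), ncol(labels))
}
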