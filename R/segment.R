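#' Segment a single frame into a worm mask
#'
#' Thresholds the frame (Otsu's method by default, or a fixed gray
#' level), keeps the largest 8-connected foreground component, and fills
#' holes (a self-overlapping omega posture can enclose background).
#'
#' @param frame A numeric matrix of gray levels (0-255).
#' @param policy `"otsu"` for automatic thresholding or `"fixed"` with
#'   an explicit `threshold`.
#' @param threshold Gray level for `policy = "fixed"`.
#' @param min_area Minimum foreground component area (px); a frame whose
#'   largest component is smaller signals a lost worm and raises an
#'   `osmodrop_empty_mask` error (callers flag the frame rather than
#'   silently dropping it).
#' @return A logical matrix mask.
#' @export
segment_frame <- function(frame, policy = c("otsu", "fixed"),
                          threshold = NULL, min_area = 30) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(frame))
  if (policy == "otsu") {
    rng <- range(frame)
    if (rng[1] == rng[2]) {
      stop_osmodrop("cannot Otsu-threshold a constant frame",
                    "osmodrop_empty_mask")
    }
    threshold <- EBImage::otsu(frame, range = rng, levels = 256)
  } else if (is.null(threshold)) {
    stop("`threshold` is required for policy = \"fixed\"")
  }
  bw <- frame > threshold
  if (!any(bw)) {
    stop_osmodrop("no foreground pixels above threshold",
                  "osmodrop_empty_mask")
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_area) {
    stop_osmodrop(sprintf(
      "largest component (%d px) below min_area = %d: lost worm",
      max(sizes), min_area), "osmodrop_empty_mask")
  }
  biggest <- (lab == which.max(sizes))
  EBImage::fillHull(biggest * 1L) > 0
}

## Segment every frame of a stack; frames where segmentation fails are
## returned as NULL (flagged), never dropped.
segment_stack <- function(stack, policy = "otsu", threshold = NULL,
                          min_area = 30) {
  lapply(seq_len(length(stack)), function(i) {
    tryCatch(
      segment_frame(get_frame(stack, i), policy = policy,
                    threshold = threshold, min_area = min_area),
      osmodrop_empty_mask = function(e) NULL
    )
  })
}

#' Measure body area from a mask
#'
#' Foreground pixel count times the squared pixel size.
#'
#' @param mask Logical matrix from [segment_frame()].
#' @param pixel_size Physical pixel edge length (default 1: px^2).
#' @return Area (pixel_size^2 units).
#' @export
measure_body_area <- function(mask, pixel_size = 1) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  n <- sum(mask)
  if (n == 0) {
    stop_osmodrop("empty mask has no area", "osmodrop_empty_mask")
  }
  n * pixel_size^2
}

#' Blind a set of image files for unbiased measurement
#'
#' Randomly reorders a list of file names and assigns
#' condition-agnostic replacement names (`blinded_001.ext`, ...), so a
#' rater can measure without knowing which condition each image belongs
#' to. The permutation is seeded and reproducible; the original-to-blind
#' mapping is returned (and optionally sealed to a separate CSV) for
#' unblinding after measurement.
#'
#' @param files Character vector of unique file names/paths.
#' @param seed Integer seed for the permutation.
#' @param mapping_file Optional path: write the sealed mapping CSV here.
#' @param rename If `TRUE` and the files exist on disk, rename them.
#' @return A list with `blinded` (new names, in randomized measurement
#'   order) and `mapping` (data frame of `original`, `blinded`).
#' @seealso [unblind()]
#' @export
blind_rename <- function(files, seed, mapping_file = NULL, rename = FALSE) {
  if (anyDuplicated(files)) stop("file names must be unique")
  n <- length(files)
  ord <- with_seed(seed, sample.int(n))
  ext <- sub("^.*\\.", "", basename(files[ord]))
  ext <- ifelse(ext == basename(files[ord]), "", paste0(".", ext))
  blinded <- file.path(dirname(files[ord]),
                       sprintf("blinded_%03d%s", seq_len(n), ext))
  if (anyDuplicated(blinded)) {
    stop("name collision after renaming; files must live in one directory ",
         "scheme with distinct targets")
  }
  if (rename) {
    ok <- file.rename(files[ord], blinded)
    if (!all(ok)) stop("failed to rename: ", files[ord][!ok][1])
  }
  mapping <- data.frame(original = files[ord], blinded = blinded,
                        stringsAsFactors = FALSE)
  if (!is.null(mapping_file)) {
    write.csv(mapping, mapping_file, row.names = FALSE)
  }
  list(blinded = blinded, mapping = mapping)
}

#' @rdname blind_rename
#' @param mapping The mapping data frame (or sealed CSV path).
#' @param blinded Blinded names to translate back.
#' @export
unblind <- function(mapping, blinded) {
  if (is.character(mapping)) mapping <- read.csv(mapping)
  idx <- match(blinded, mapping$blinded)
  if (anyNA(idx)) stop("unknown blinded name: ", blinded[is.na(idx)][1])
  mapping$original[idx]
}
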