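#' Binarize a grayscale stimulus image
#'
#' Converts a grayscale intensity grid to an ink mask: a pixel is ink when
#' its intensity falls strictly below the cutoff (dark text on a light
#' background; set `invert = TRUE` for light-on-dark stimuli).
#'
#' @param img Numeric/integer matrix (rows x cols) with intensities 0-255.
#' @param cutoff Intensity threshold (default 128).
#' @param invert Treat bright pixels as ink (default FALSE).
#' @return Logical matrix, `TRUE` where ink.
#' @export
binarize <- function(img, cutoff = 128, invert = FALSE) {
  if (!is.matrix(img) || length(img) == 0) stop("img must be a non-empty matrix")
  if (min(img) < 0 || max(img) > 255) stop("intensities must be in [0, 255]")
  if (invert) img > (255 - cutoff) else img < cutoff
}

# Split positions 1..n flagged by `active` into groups: a gap of inactive
# positions strictly longer than `gap` starts a new group. Returns a list
# of integer ranges (first, last active position of each group).
split_on_gaps <- function(active, gap) {
  pos <- which(active)
  if (length(pos) == 0) return(list())
  brk <- which(diff(pos) > gap + 1)   # gap run length = diff - 1 > gap
  starts <- c(1, brk + 1)
  ends <- c(brk, length(pos))
  lapply(seq_along(starts), function(i) c(pos[starts[i]], pos[ends[i]]))
}

#' Detect areas of interest in a text stimulus image
#'
#' Threshold-scan AOI detection: the binarized image is scanned vertically
#' to group ink rows into line bands (a blank-row run strictly longer than
#' `height_threshold` separates bands), then each band is scanned
#' horizontally (a blank-column run strictly longer than `width_threshold`
#' separates AOIs). Small thresholds give letter granularity, larger ones
#' whole words; `level = "line"` emits a single AOI per band. Detected
#' AOIs carry 1-based `line` (top to bottom) and `part` (left to right)
#' indices; each AOI's height spans its whole band (plus `height_pad` on
#' both sides).
#'
#' @param img Grayscale intensity matrix (rows x cols, 0-255).
#' @param level Granularity: `"letter"`, `"word"` or `"line"`.
#' @param width_threshold Horizontal blank run (pixels) that splits AOIs;
#'   default 2 for letters, 8 for words (unused for lines).
#' @param height_threshold Vertical blank run (pixels) that splits line
#'   bands (default 10).
#' @param binarize_cutoff,invert Passed to [binarize()] (defaults 128,
#'   FALSE).
#' @param height_pad Extra pixels added above and below each band
#'   (default 0).
#' @param image Stimulus identifier attached to the AOIs.
#' @return An [aoi_set].
#' @examples
#' fix <- make_stimulus_fixture(n_lines = 2, words_per_line = 3)
#' detected <- detect_aois(fix$image, "word")
#' nrow(detected) == nrow(fix$aois)
#' @export
detect_aois <- function(img, level = c("word", "letter", "line"),
                        width_threshold = NULL, height_threshold = 10,
                        binarize_cutoff = 128, invert = FALSE,
                        height_pad = 0, image = "stimulus") {
  level <- match.arg(level)
  if (is.null(width_threshold))
    width_threshold <- switch(level, letter = 2, word = 8, line = Inf)
  if (level != "line" && width_threshold < 1) stop("width_threshold must be >= 1")
  if (height_threshold < 1) stop("height_threshold must be >= 1")
  ink <- binarize(img, binarize_cutoff, invert)
  if (!any(ink)) stop("no ink regions")
  bands <- split_on_gaps(apply(ink, 1, any), height_threshold)
  xs <- ys <- ws <- hs <- ln <- pt <- c()
  for (b in seq_along(bands)) {
    rows <- bands[[b]][1]:bands[[b]][2]
    col_active <- apply(ink[rows, , drop = FALSE], 2, any)
    groups <- if (level == "line") {
      p <- range(which(col_active)); list(p)
    } else split_on_gaps(col_active, width_threshold)
    for (g in seq_along(groups)) {
      # pixel row/col r covers coordinate interval [r-1, r)
      xs <- c(xs, groups[[g]][1] - 1)
      ws <- c(ws, groups[[g]][2] - groups[[g]][1] + 1)
      ys <- c(ys, bands[[b]][1] - 1 - height_pad)
      hs <- c(hs, bands[[b]][2] - bands[[b]][1] + 1 + 2 * height_pad)
      ln <- c(ln, b); pt <- c(pt, g)
    }
  }
  aoi_set(level, xs, ys, ws, hs, ln, pt, image = image,
          screen_width = ncol(img), screen_height = nrow(img))
}

#' Read a stimulus image as a grayscale matrix
#'
#' Loads a PNG or TIFF bitmap and converts it to a grayscale intensity
#' matrix (0-255) by averaging color channels.
#'
#' @param path Path to a `.png` or `.tif`/`.tiff` file.
#' @return Numeric matrix (rows x cols), intensities 0-255.
#' @export
read_stimulus <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    tif = , tiff = { requireNamespace("tiff"); tiff::readTIFF(path) },
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3) {
    nch <- min(dim(arr)[3], 3)       # drop alpha
    arr <- apply(arr[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  arr * 255
}

#' Write an AOI set to CSV
#'
#' Writes one AOI per row with columns
#' `kind,name,x,y,width,height,image` where `name` encodes the line and
#' part (`"line 1 part 2"`); the file can be edited externally and read
#' back with [read_aoi_csv()].
#'
#' @param aois An [aoi_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aoi_csv <- function(aois, path) {
  df <- data.frame(kind = aois$kind,
                   name = sprintf("line %d part %d", aois$line, aois$part),
                   x = aois$x, y = aois$y, width = aois$width,
                   height = aois$height, image = aois$image,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an AOI set from CSV
#'
#' Inverse of [write_aoi_csv()].
#'
#' @param path CSV path.
#' @param screen_width,screen_height Optional stimulus dimensions.
#' @return An [aoi_set].
#' @export
read_aoi_csv <- function(path, screen_width = NA, screen_height = NA) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "name", "x", "y", "width", "height", "image")
  if (!all(need %in% names(df)))
    stop("AOI CSV must have columns: ", paste(need, collapse = ", "))
  m <- regmatches(df$name, regexec("line ([0-9]+) part ([0-9]+)", df$name))
  line <- vapply(m, function(v) as.integer(v[2]), integer(1))
  part <- vapply(m, function(v) as.integer(v[3]), integer(1))
  if (anyNA(line) || anyNA(part))
    stop("AOI names must look like 'line <i> part <j>'")
  aoi_set(df$kind[1], df$x, df$y, df$width, df$height, line, part,
          image = df$image, screen_width = screen_width,
          screen_height = screen_height)
}
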