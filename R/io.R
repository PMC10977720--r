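# Disk interchange: stimulus sets as a directory of PNG images plus a CSV
# metadata table, response matrices as CSV with a neuron-id header row.

#' Write / read a stimulus set as PNG files plus metadata CSV
#'
#' The directory layout is one grayscale PNG per image (named
#' `<image_id>.png`) and a `metadata.csv` with columns `image_id`, `valence`,
#' `category`, `dataset`.
#'
#' @param stimuli a `stimulus_set`.
#' @param dir directory (created if missing).
#' @return `dir` (write) or the reloaded `stimulus_set` (read).
#' @export
write_stimulus_set <- function(stimuli, dir) {
  assert_that(inherits(stimuli, "stimulus_set"), "not a stimulus_set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(stimuli$meta))) {
    png::writePNG(stimuli$images[, , i],
                  file.path(dir, paste0(stimuli$meta$image_id[i], ".png")))
  }
  utils::write.csv(stimuli$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  assert_that(all(c("image_id", "valence", "category", "dataset") %in%
                    names(meta)), "metadata.csv lacks required columns")
  first <- png::readPNG(file.path(dir, paste0(meta$image_id[1L], ".png")))
  if (length(dim(first)) == 3L) first <- first[, , 1L]
  imgs <- array(0, dim = c(nrow(first), ncol(first), nrow(meta)))
  for (i in seq_len(nrow(meta))) {
    im <- png::readPNG(file.path(dir, paste0(meta$image_id[i], ".png")))
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    imgs[, , i] <- im
  }
  stimulus_set(imgs, meta$valence, meta$category,
               dataset = meta$dataset[1L], image_id = meta$image_id)
}

#' Export / import a response matrix as CSV
#'
#' The header row carries neuron identifiers (`L<layer>.K<filter>`); the
#' first column holds image identifiers.
#'
#' @param responses a `response_matrix`.
#' @param path CSV file path.
#' @return `path` (write) or the reloaded `response_matrix` (read).
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(image_id = rownames(responses), responses,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @param layer,dataset attributes to attach on read (layer defaults to the
#'   value parsed from the first neuron id).
#' @export
read_responses <- function(path, layer = NULL, dataset = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$image_id
  if (is.null(layer)) {
    layer <- as.integer(sub("^L(\\d+)\\..*", "\\1", colnames(m)[1L]))
  }
  attr(m, "layer") <- layer
  attr(m, "dataset") <- dataset
  class(m) <- c("response_matrix", class(m))
  m
}
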