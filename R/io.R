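#' Write a calcium dataset to a directory of CSV/JSON files
#'
#' Plain-text serialization of a `calcium_dataset`: `traces.csv` (neurons x
#' frames), `neurons.csv` (positions, region id and ground truth when
#' present), `schedule.csv`, `regions.csv`, `meta.json`. Intended for
#' datasets up to about 1e6 trace cells; larger recordings should be
#' regenerated from their seed instead.
#'
#' @param dataset A `calcium_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_calcium_dataset <- function(dataset, dir) {
  if (length(dataset$traces) > 1e6)
    stop("trace matrix exceeds 1e6 cells; regenerate from seed instead")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$traces, file.path(dir, "traces.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  neurons <- data.frame(x = dataset$positions[, 1],
                        y = dataset$positions[, 2],
                        region = dataset$region)
  if (!is.null(dataset$ground_truth)) {
    neurons$preferred <- dataset$ground_truth$preferred
    neurons$responsive <- dataset$ground_truth$responsive
    neurons$community <- dataset$ground_truth$community
  }
  utils::write.csv(neurons, file.path(dir, "neurons.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$schedule),
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  utils::write.csv(dataset$region_map$rects, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  meta <- list(frame_rate = dataset$frame_rate,
               stim_duration = attr(dataset$schedule, "stim_duration"),
               orientations = attr(dataset$schedule, "orientations"),
               sheet = c(dataset$region_map$width, dataset$region_map$height))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a calcium dataset written by [write_calcium_dataset()]
#' @param dir Directory containing the CSV/JSON files.
#' @return A `calcium_dataset`.
#' @export
read_calcium_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  traces <- as.matrix(utils::read.table(file.path(dir, "traces.csv"),
                                        sep = ","))
  dimnames(traces) <- NULL
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"))
  sched <- utils::read.csv(file.path(dir, "schedule.csv"))
  attr(sched, "stim_duration") <- meta$stim_duration
  attr(sched, "orientations") <- meta$orientations
  class(sched) <- c("stim_schedule", "data.frame")
  rects <- utils::read.csv(file.path(dir, "regions.csv"))
  map <- structure(list(width = meta$sheet[1], height = meta$sheet[2],
                        n_regions = nrow(rects), rects = rects),
                   class = "region_map")
  gt <- NULL
  if ("preferred" %in% names(neurons))
    gt <- list(preferred = neurons$preferred,
               responsive = neurons$responsive,
               community = neurons$community)
  structure(list(traces = traces, frame_rate = meta$frame_rate,
                 positions = cbind(neurons$x, neurons$y),
                 region = neurons$region, region_map = map,
                 schedule = sched, ground_truth = gt),
            class = "calcium_dataset")
}

#' Write a functional network as a square-matrix CSV
#' @param net A `functional_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  utils::write.csv(as.data.frame(net$w), path, row.names = TRUE)
  invisible(path)
}

#' Read a functional network from a square-matrix CSV
#' @param path File written by [write_network_csv()].
#' @param level Node level tag.
#' @return A `functional_network`.
#' @export
read_network_csv <- function(path, level = "region") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  structure(list(w = m, nodes = rownames(m), level = level),
            class = "functional_network")
}
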