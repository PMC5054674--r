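#' Write a cine sequence to the CSV + sidecar JSON interchange format
#'
#' One CSV per subject with columns `frame_index`, `time_ms`,
#' `landmark_index`, `x`, `y`, `z` (mm), and a sidecar JSON carrying the
#' ring/apex topology, event times and metadata. Frame and landmark indices
#' are 0-based in the files.
#'
#' @param cine a [cine_sequence()].
#' @param csv_path,json_path output paths; `json_path` defaults to the CSV
#'   path with a `.json` extension.
#' @return invisibly, the two paths.
#' @export
write_cine <- function(cine, csv_path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.csv$", ".json", csv_path)
  k <- nrow(cine$frames[[1L]])
  tab <- do.call(rbind, lapply(seq_along(cine$frames), function(i)
    data.frame(frame_index = i - 1L, time_ms = cine$times[i],
               landmark_index = seq_len(k) - 1L,
               x = cine$frames[[i]][, 1L], y = cine$frames[[i]][, 2L],
               z = cine$frames[[i]][, 3L])))
  write.csv(tab, csv_path, row.names = FALSE)
  topo <- config_topology(cine$frames[[1L]])
  meta <- list(subject_id = cine$subject_id, group = cine$group,
               rings = topo$rings, points_per_ring = topo$points_per_ring,
               apex_index = topo$apex_index,
               events = list(R = cine$events$t_R, ED = cine$events$t_ED,
                             P = cine$events$t_P,
                             R_next = cine$events$t_R_next))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a cine sequence from the CSV + sidecar JSON format
#'
#' @param csv_path,json_path paths written by [write_cine()].
#' @return a [cine_sequence()].
#' @export
read_cine <- function(csv_path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.csv$", ".json", csv_path)
  tab <- read.csv(csv_path)
  need <- c("frame_index", "time_ms", "landmark_index", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("invalid cine CSV: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  idx <- sort(unique(tab$frame_index))
  frames <- lapply(idx, function(i) {
    fr <- tab[tab$frame_index == i, ]
    fr <- fr[order(fr$landmark_index), ]
    landmark_config(cbind(fr$x, fr$y, fr$z),
                    rings = meta$rings, points_per_ring = meta$points_per_ring,
                    apex_index = meta$apex_index)
  })
  times <- vapply(idx, function(i)
    tab$time_ms[match(i, tab$frame_index)], 0)
  ev <- event_annotations(meta$events$R, meta$events$ED, meta$events$P,
                          meta$events$R_next)
  cine_sequence(frames, times, ev, meta$subject_id,
                group = meta$group %||% "unknown")
}
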