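# Plain-text exports mirroring the tabular interfaces of the pipeline.

#' Write interactions as CSV
#' @param interactions interaction data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_interactions <- function(interactions, path) {
  utils::write.csv(interactions, path, row.names = FALSE)
  invisible(path)
}

#' Write a constraint network as an edge-list TSV
#' @param net a [constraint_network()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  utils::write.table(net$bars, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an unfolding trajectory as TSV (state, E_cut, T, P_inf, clusters)
#' @param traj an `unfolding_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj$states, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stability map as sparse CSV
#' @param map a [stability_map()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stability_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
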