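#' Build an undirected weekly interaction network
#'
#' Reconciles the two directions of a badge interaction log into an
#' undirected weighted graph for one work week. Sociometric detectors are
#' imperfect: one badge of a pair frequently logs a contact the other
#' misses. For every unordered pair \{a, b\} the edge weight is the *minimum*
#' of the two directed counts — the number of contacts both detectors agree
#' on:
#' \deqn{w(a,b) = \min(c_{ab}, c_{ba})}
#' where \eqn{c_{ab}} counts records with logger a and detected b. Pairs with
#' a zero minimum get no edge, and participants left with no edge get no
#' node.
#'
#' @param records Data.frame of interaction records for a single week
#'   (columns `logger_id`, `detected_id`).
#' @param week_index Optional week index stored as a graph attribute.
#' @return An [igraph::igraph] undirected graph with integer `weight` edge
#'   attribute; the empty graph when no pair is reciprocated.
#' @export
build_weekly_network <- function(records, week_index = NA_integer_) {
  if (nrow(records) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g$week_index <- week_index
    return(g)
  }
  a <- as.character(records$logger_id)
  b <- as.character(records$detected_id)
  # directed counts per ordered pair
  key <- paste(a, b, sep = "\r")
  cnt <- table(key)
  pair <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  dir_counts <- data.frame(from = pair[, 1], to = pair[, 2],
                           n = as.integer(cnt), stringsAsFactors = FALSE)
  # reconcile: weight = min over the two directions
  lo <- pmin(dir_counts$from, dir_counts$to)
  hi <- pmax(dir_counts$from, dir_counts$to)
  ukey <- paste(lo, hi, sep = "\r")
  w_ab <- tapply(ifelse(dir_counts$from == lo, dir_counts$n, 0L), ukey, sum)
  w_ba <- tapply(ifelse(dir_counts$from == lo, 0L, dir_counts$n), ukey, sum)
  w <- pmin(w_ab, w_ba)
  keep <- w >= 1
  if (!any(keep)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g$week_index <- week_index
    return(g)
  }
  up <- do.call(rbind, strsplit(names(w)[keep], "\r", fixed = TRUE))
  el <- data.frame(from = up[, 1], to = up[, 2],
                   weight = as.integer(w[keep]), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  g$week_index <- week_index
  g
}

#' Build all weekly networks
#'
#' @param records Interaction records with a `week` column (see
#'   [split_work_weeks()]).
#' @param weeks Work-week calendar; one (possibly empty) network per row.
#' @return Named list of weekly [igraph::igraph] graphs, names `"1"`,
#'   `"2"`, ...
#' @export
build_weekly_networks <- function(records, weeks) {
  out <- lapply(weeks$week, function(w) {
    build_weekly_network(records[records$week == w, , drop = FALSE],
                         week_index = w)
  })
  names(out) <- as.character(weeks$week)
  out
}

#' Extract an egocentric network
#'
#' The ego network of a participant is the vertex-induced subgraph on the
#' ego plus all its direct neighbours (alters); alter--alter edges of the
#' parent network are retained with their weights.
#'
#' @param net Weekly network from [build_weekly_network()].
#' @param ego Participant id (vertex name).
#' @return An igraph graph with graph attribute `ego` set, or `NULL` when
#'   the ego has no node that week (no reconciled interaction).
#' @export
extract_ego_network <- function(net, ego) {
  ego <- as.character(ego)
  if (!(ego %in% igraph::V(net)$name)) return(NULL)
  nbrs <- igraph::neighbors(net, ego)
  sub <- igraph::induced_subgraph(net, c(ego, nbrs$name))
  sub$ego <- ego
  sub
}

#' Write and read weekly networks
#'
#' Each weekly network is exported both as GraphML (with the `weight` edge
#' attribute) and as a plain whitespace-delimited weighted edge list
#' (`a b w`), one pair of files per week named by week index.
#'
#' @param networks Named list of weekly graphs.
#' @param dir Output directory (created if needed).
#' @return `write_weekly_networks` returns the directory invisibly;
#'   `read_weekly_networks` returns the named list of graphs.
#' @export
write_weekly_networks <- function(networks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in names(networks)) {
    g <- networks[[w]]
    igraph::write_graph(g, file.path(dir, paste0("week_", w, ".graphml")),
                        format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    write.table(el[c("from", "to", "weight")],
                file.path(dir, paste0("week_", w, ".edges")),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_weekly_networks
#' @param format `"graphml"` or `"edges"`.
#' @export
read_weekly_networks <- function(dir, format = c("graphml", "edges")) {
  format <- match.arg(format)
  ext <- paste0(".", if (format == "graphml") "graphml" else "edges")
  files <- list.files(dir, pattern = paste0("^week_\\d+\\", ext, "$"))
  if (length(files) == 0) stop("no week_*", ext, " files in ", dir)
  idx <- as.integer(sub(paste0("^week_(\\d+)\\", ext, "$"), "\\1", files))
  files <- files[order(idx)]
  idx <- sort(idx)
  out <- lapply(seq_along(files), function(i) {
    path <- file.path(dir, files[i])
    if (format == "graphml") {
      g <- igraph::read_graph(path, format = "graphml")
    } else {
      el <- read.table(path, col.names = c("from", "to", "weight"),
                       colClasses = c("character", "character", "numeric"))
      g <- igraph::graph_from_data_frame(el, directed = FALSE)
    }
    g$week_index <- idx[i]
    g
  })
  names(out) <- as.character(idx)
  out
}
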