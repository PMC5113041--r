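# Rebuilding the mother-daughter cell lineage from a snapshot stream, and
# exporting / rendering it.

new_lineage_tree <- function(df, end_time) {
  df <- as_tibble(df)
  internal <- !is.na(df$divided)
  if (any(internal & df$divided <= df$born)) {
    bad <- df$name[which(internal & df$divided <= df$born)[1L]]
    rlang::abort(sprintf("lineage tree: cell %s has non-positive cycle length", bad),
                 class = "elegansim_structural_error")
  }
  # daughters' birth must coincide with the parent's division
  i <- match(df$parent, df$name)
  has_parent <- !is.na(i)
  if (any(has_parent & abs(df$born - df$divided[i]) > 1e-9, na.rm = TRUE)) {
    rlang::abort("lineage tree: daughter birth time does not match parent division time",
                 class = "elegansim_structural_error")
  }
  structure(df, end_time = end_time,
            class = c("lineage_tree", class(tibble::tibble())))
}

#' Rebuild the cell lineage from a snapshot stream
#'
#' Cells are tracked across time points through the predecessor indices of
#' the 20-field format: a record whose predecessor carries two successors is
#' a newborn daughter of that predecessor. A cell's `born` time is the first
#' snapshot in which it appears, and its `divided` time is the snapshot at
#' which its daughters first appear, so times are quantized to the snapshot
#' resolution of the stream.
#'
#' @param snapshots A snapshot tibble ([simulate_embryo()]'s `$snapshots`,
#'   or [read_snapshot()] output), or an `embryo_sim` object.
#' @return A `lineage_tree`: a tibble with columns `name`, `parent` (`NA`
#'   for roots), `daughter1`, `daughter2` (`NA` for leaves), `born`,
#'   `divided` (`NA` for leaves), in seconds; the stream's final time is
#'   attached as attribute `end_time`.
#' @export
build_lineage <- function(snapshots) {
  if (inherits(snapshots, "embryo_sim")) snapshots <- snapshots$snapshots
  snapshots <- as_tibble(snapshots)
  times <- sort(unique(snapshots$time))
  if (length(times) == 0L) {
    return(new_lineage_tree(tibble(
      name = character(), parent = character(),
      daughter1 = character(), daughter2 = character(),
      born = double(), divided = double()
    ), end_time = NA_real_))
  }
  by_time <- lapply(times, function(tp) {
    s <- snapshots[snapshots$time == tp, , drop = FALSE]
    s[order(s$index), , drop = FALSE]
  })

  born <- divided <- stats::setNames(numeric(0), character(0))
  parent <- stats::setNames(character(0), character(0))
  kids <- list()
  for (k in seq_along(by_time)) {
    s <- by_time[[k]]
    for (j in seq_len(nrow(s))) {
      nm <- s$name[j]
      if (!(nm %in% names(born))) {
        born[nm] <- times[k]
        if (k > 1L) {
          pv <- s$prev[j]
          before <- by_time[[k - 1L]]
          if (pv < 1L || pv > nrow(before)) {
            rlang::abort(sprintf(
              "snapshot stream: dangling predecessor index %d at time %g", pv, times[k]
            ), class = "elegansim_structural_error")
          }
          pname <- before$name[pv]
          parent[nm] <- pname
          if (!(pname %in% names(divided))) divided[pname] <- times[k]
          kids[[pname]] <- c(kids[[pname]], nm)
        }
      } else if (k > 1L) {
        pv <- s$prev[j]
        if (pv < 1L || pv > nrow(by_time[[k - 1L]])) {
          rlang::abort(sprintf(
            "snapshot stream: dangling predecessor index %d at time %g", pv, times[k]
          ), class = "elegansim_structural_error")
        }
      }
    }
  }
  over <- names(kids)[lengths(kids) > 2L]
  if (length(over) > 0L) {
    rlang::abort(sprintf("snapshot stream: cell %s has more than two daughters",
                         over[1L]),
                 class = "elegansim_structural_error")
  }
  nms <- names(born)
  d1 <- vapply(nms, function(n) if (is.null(kids[[n]])) NA_character_ else kids[[n]][1L], character(1))
  d2 <- vapply(nms, function(n) if (is.null(kids[[n]]) || length(kids[[n]]) < 2L) NA_character_ else kids[[n]][2L], character(1))
  single <- !is.na(d1) & is.na(d2)
  if (any(single)) {
    rlang::abort(sprintf("snapshot stream: cell %s has a single daughter (daughters must come in pairs)",
                         nms[which(single)[1L]]),
                 class = "elegansim_structural_error")
  }
  new_lineage_tree(tibble(
    name = nms,
    parent = unname(parent[nms]),
    daughter1 = unname(d1), daughter2 = unname(d2),
    born = unname(born[nms]),
    divided = unname(divided[nms])
  ), end_time = max(times))
}

#' Cell cycle length of one cell
#'
#' The time from a cell's birth (its mother's division) to its own division.
#'
#' @param tree A `lineage_tree`.
#' @param name Cell name; must be an internal node (a cell that divided).
#' @return Cycle length in seconds.
#' @export
cell_cycle <- function(tree, name) {
  i <- match(name, tree$name)
  if (is.na(i)) {
    rlang::abort(sprintf("cell %s is not in the lineage tree", name),
                 class = "elegansim_lookup_error")
  }
  if (is.na(tree$divided[i])) {
    rlang::abort(sprintf("cell %s never divides (leaf); it has no cycle length", name),
                 class = "elegansim_lookup_error")
  }
  tree$divided[i] - tree$born[i]
}

lineage_roots <- function(tree) tree$name[is.na(tree$parent)]

fmt_len <- function(x) sprintf("%.10g", x)

#' Export a lineage tree as Newick text
#'
#' Branch lengths are cell-cycle durations (for leaves, the time from birth
#' to the end of observation). The four founders of an embryo give a forest:
#' one Newick string is emitted per root. A root with no divisions is
#' emitted as `"name:0;"`.
#'
#' @param tree A `lineage_tree`.
#' @return Character vector, one Newick string per root.
#' @export
to_newick <- function(tree) {
  end_time <- attr(tree, "end_time")
  i_of <- stats::setNames(seq_len(nrow(tree)), tree$name)
  emit <- function(nm, is_root) {
    i <- i_of[[nm]]
    if (is.na(tree$divided[i])) {
      len <- if (is_root) 0 else end_time - tree$born[i]
      sprintf("%s:%s", nm, fmt_len(len))
    } else {
      len <- tree$divided[i] - tree$born[i]
      sprintf("(%s,%s)%s:%s",
              emit(tree$daughter1[i], FALSE), emit(tree$daughter2[i], FALSE),
              nm, fmt_len(len))
    }
  }
  vapply(lineage_roots(tree), function(r) paste0(emit(r, TRUE), ";"),
         character(1), USE.NAMES = FALSE)
}

# deterministic layout: leaves in lineage order get consecutive x slots,
# internal nodes sit at the mean of their daughters
lineage_layout <- function(tree) {
  i_of <- stats::setNames(seq_len(nrow(tree)), tree$name)
  xpos <- stats::setNames(rep(NA_real_, nrow(tree)), tree$name)
  slot <- 0
  assign_x <- function(nm) {
    i <- i_of[[nm]]
    if (is.na(tree$daughter1[i])) {
      slot <<- slot + 1
      xpos[nm] <<- slot
    } else {
      assign_x(tree$daughter1[i])
      assign_x(tree$daughter2[i])
      xpos[nm] <<- (xpos[tree$daughter1[i]] + xpos[tree$daughter2[i]]) / 2
    }
  }
  for (r in lineage_roots(tree)) assign_x(r)
  xpos
}

#' Draw a cell lineage tree
#'
#' Vertical line length is proportional to cell-cycle time (time increases
#' downward); horizontal bars join sister cells at the moment of division,
#' so sublineages dividing at different paces are immediately visible.
#' Founders are drawn side by side. The layout is deterministic.
#'
#' @param tree A `lineage_tree`.
#' @return A ggplot object.
#' @export
plot_lineage <- function(tree) {
  end_time <- attr(tree, "end_time")
  if (nrow(tree) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  xpos <- lineage_layout(tree)
  df <- tibble(
    name = tree$name,
    x = unname(xpos[tree$name]),
    y0 = tree$born,
    y1 = ifelse(is.na(tree$divided),
                if (is.na(end_time)) tree$born else end_time,
                tree$divided)
  )
  internal <- tree[!is.na(tree$divided), , drop = FALSE]
  bars <- tibble(
    x0 = unname(xpos[internal$daughter1]),
    x1 = unname(xpos[internal$daughter2]),
    y = internal$divided
  )
  leaves <- df[tree$name %in% tree$name[is.na(tree$daughter1)], , drop = FALSE]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = df,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$y0, yend = .data$y1)) +
    ggplot2::geom_segment(data = bars,
                          ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = .data$y1, label = .data$name),
                       angle = 90, hjust = 1.1, size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "time (s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor.x = ggplot2::element_blank())
}

#' @export
autoplot.lineage_tree <- function(object, ...) plot_lineage(object)
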