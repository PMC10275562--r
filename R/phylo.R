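# Phylogeny bookkeeping: the simulator logs (time, event, species, parent)
# rows; a speciation creates one child branching off the parent lineage, an
# extinction closes a lineage. Trees are emitted in Newick via ape. The
# exported tree is the crown tree of the retained tips; the stem from time 0
# to the first split is stored as the root edge.

# the in-flight log is a list of one-row records (cheap to append);
# finalize_log() turns it into the events data.frame
empty_log <- function() list()

log_event <- function(log, time, event, sp, parent = NA_integer_) {
  log[[length(log) + 1L]] <- list(time = time, event = event,
                                  sp = as.integer(sp),
                                  parent = as.integer(parent))
  log
}

finalize_log <- function(log) {
  if (!length(log))
    return(data.frame(time = numeric(0), event = character(0),
                      sp = integer(0), parent = integer(0)))
  data.frame(time = vapply(log, `[[`, numeric(1), "time"),
             event = vapply(log, `[[`, character(1), "event"),
             sp = vapply(log, `[[`, integer(1), "sp"),
             parent = vapply(log, `[[`, integer(1), "parent"))
}

#' Convert a phylogeny log to an ape tree
#'
#' Branch lengths are in time steps (multiply by the step duration for
#' absolute time). With `drop_extinct = TRUE` only extant lineages are kept.
#' Returns `NULL` when fewer than two tips remain; tips are labelled
#' `s<species id>`.
#'
#' @param events data.frame with columns time, event ("speciation" or
#'   "extinction"), sp, parent.
#' @param final_time time of the last simulated step.
#' @param drop_extinct drop lineages extinct before `final_time`.
#' @return an object of class `phylo`, or `NULL`.
#' @export
phylo_from_log <- function(events, final_time, drop_extinct = TRUE) {
  spec <- events[events$event == "speciation", , drop = FALSE]
  ext <- events[events$event == "extinction", , drop = FALSE]
  if (nrow(spec) == 0L) return(NULL)
  spec$kind <- "s"
  ext$kind <- if (nrow(ext)) "e" else character(0)
  ev <- rbind(spec, ext)
  ev <- ev[order(ev$time, seq_len(nrow(ev))), , drop = FALSE]

  # node store: parent id, edge length leading in, label ("" for internal)
  par <- integer(0); len <- numeric(0); lab <- character(0)
  new_node <- function(p, l, la) {
    par[length(par) + 1L] <<- p
    len[length(len) + 1L] <<- l
    lab[length(lab) + 1L] <<- la
    length(par)
  }
  open_node <- c(`1` = 0L)       # species id -> node its branch extends from
  open_time <- c(`1` = 0)
  root_time <- NA_real_
  for (i in seq_len(nrow(ev))) {
    t <- ev$time[i]; s <- as.character(ev$sp[i])
    if (ev$kind[i] == "s") {
      p <- as.character(ev$parent[i])
      v <- new_node(open_node[[p]], t - open_time[[p]], "")
      if (is.na(root_time)) root_time <- t
      open_node[[p]] <- v; open_time[[p]] <- t
      open_node[[s]] <- v; open_time[[s]] <- t
    } else {
      if (is.null(open_node[[s]])) return(NULL)  # lone root dies pre-split
      new_node(open_node[[s]], t - open_time[[s]], paste0("s", s))
      open_node[[s]] <- NA_integer_
    }
  }
  for (s in names(open_node)) {
    if (is.na(open_node[[s]])) next
    new_node(open_node[[s]], final_time - open_time[[s]], paste0("s", s))
  }

  # newick via iterative post-order string assembly
  kids <- split(seq_along(par), factor(par, levels = 0:length(par)))
  str <- character(length(par))
  done_kids <- integer(length(par))
  piece <- function(v) {
    if (lab[v] != "") return(paste0(lab[v], ":", format(len[v], digits = 15)))
    inner <- paste0("(", paste(str[kids[[v + 1L]]], collapse = ","), ")")
    if (par[v] == 0L) inner    # stem length goes to root.edge instead
    else paste0(inner, ":", format(len[v], digits = 15))
  }
  # process nodes: repeatedly finish nodes whose children are all done
  n_children <- lengths(kids)[-1L]
  ready <- which(n_children == 0L)
  remaining <- rep(TRUE, length(par))
  while (length(ready)) {
    nxt <- integer(0)
    for (v in ready) {
      str[v] <- piece(v)
      remaining[v] <- FALSE
      p <- par[v]
      if (p > 0L) {
        done_kids[p] <- done_kids[p] + 1L
        if (done_kids[p] == n_children[p]) nxt <- c(nxt, p)
      }
    }
    ready <- nxt
  }
  root_kids <- kids[["0"]]
  txt <- paste0(str[root_kids], ";")
  tr <- ape::read.tree(text = txt)
  tr$root.edge <- root_time
  if (drop_extinct) {
    extinct <- paste0("s", ext$sp)
    extinct <- intersect(extinct, tr$tip.label)
    if (length(extinct)) {
      if (length(setdiff(tr$tip.label, extinct)) < 2L) return(NULL)
      tr <- ape::drop.tip(tr, extinct)
    }
  }
  tr
}
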