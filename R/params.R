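# Parameter-tree plumbing: every learnable array lives at
# stage$blocks$<...>$par$<name>; gradient trees returned by the backward
# passes mirror the same structure minus the "blocks"/"par" wrappers.

enumerate_params_ <- function(stage) {
  out <- list()
  walk <- function(node, path) {
    if (!is.list(node)) return()
    if (!is.null(node$par)) {
      for (nm in names(node$par)) out[[length(out) + 1L]] <<- c(path, list("par", nm))
      return()
    }
    keys <- if (is.null(names(node))) seq_along(node) else names(node)
    for (i in seq_along(node)) {
      k <- if (is.character(keys)) keys[i] else i
      if (is.character(k) && k %in% c("config", "mu")) next
      if (is.list(node[[i]])) walk(node[[i]], c(path, list(k)))
    }
  }
  walk(stage$blocks, list("blocks"))
  out
}

get_path_ <- function(x, path) {
  for (p in path) {
    x <- x[[p]]
    if (is.null(x)) return(NULL)
  }
  x
}

set_path_ <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- set_path_(x[[path[[1]]]], path[-1], value)
  x
}

# parameter path -> matching path into a gradient tree
grad_path_ <- function(path) {
  n <- length(path)
  c(path[2:(n - 2)], path[n])
}

# elementwise sum of two gradient trees of identical shape
add_trees_ <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) a[[i]] <- add_trees_(a[[i]], b[[i]])
  a
}

scale_tree_ <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  for (i in seq_along(a)) a[[i]] <- scale_tree_(a[[i]], s)
  a
}
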