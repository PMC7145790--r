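#' Areal adjacency graphs
#'
#' An `area_graph` holds the areal units of a study region together with their
#' neighbourhood structure: the backbone of every spatial computation in the
#' package (ICAR scaling, BYM2 random effects, synthetic-field generation).
#' Adjacency is stored as a symmetric neighbour list, the same information a
#' GAL file carries.
#'
#' @param neighbours A list, one element per area, each an integer vector of
#'   neighbour positions (1-based indices into `area_ids`). Must be symmetric
#'   and free of self-loops.
#' @param area_ids Character vector of unique area identifiers. Defaults to
#'   `"a1" ... "an"`.
#' @param coords Optional two-column matrix of representative coordinates
#'   (used only for plotting and GeoJSON export).
#'
#' @return An object of class `area_graph`: a list with elements `area_ids`,
#'   `neighbours` (integer index lists), `component` (integer component label
#'   per area), `n_components`, and optionally `coords`.
#' @examples
#' g <- area_graph(list(2L, c(1L, 3L), 2L), area_ids = c("A", "B", "C"))
#' g$n_components
#' @export
area_graph <- function(neighbours, area_ids = NULL, coords = NULL) {
  n <- length(neighbours)
  if (is.null(area_ids)) area_ids <- paste0("a", seq_len(n))
  area_ids <- as.character(area_ids)
  if (length(area_ids) != n) {
    stop("`area_ids` must have one entry per neighbour list element.", call. = FALSE)
  }
  if (anyDuplicated(area_ids)) {
    stop("`area_ids` must be unique.", call. = FALSE)
  }
  neighbours <- lapply(neighbours, function(x) sort(unique(as.integer(x))))
  for (i in seq_len(n)) {
    nb <- neighbours[[i]]
    if (length(nb) == 0L) next
    if (any(nb < 1L | nb > n)) {
      stop("Neighbour index out of range for area ", area_ids[i], ".", call. = FALSE)
    }
    if (any(nb == i)) {
      stop("Self-loop at area ", area_ids[i], ".", call. = FALSE)
    }
    for (j in nb) {
      if (!i %in% neighbours[[j]]) {
        stop("Asymmetric adjacency: ", area_ids[i], " lists ", area_ids[j],
             " but not vice versa.", call. = FALSE)
      }
    }
  }
  comp <- label_components(neighbours)
  structure(
    list(area_ids = area_ids, neighbours = neighbours,
         component = comp, n_components = max(comp), coords = coords),
    class = "area_graph"
  )
}

# connected-component labels by breadth-first search
label_components <- function(neighbours) {
  n <- length(neighbours)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in neighbours[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- k
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' @export
print.area_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$neighbours)) / 2
  cat("<area_graph> ", length(x$area_ids), " areas, ", n_edges, " edges, ",
      x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

#' Number of areas in an area graph
#' @param g An `area_graph`.
#' @return Integer count of areas.
#' @export
n_areas <- function(g) {
  stopifnot(inherits(g, "area_graph"))
  length(g$area_ids)
}

#' Edge list of an area graph as a tibble
#' @param x An `area_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to` (area ids), one row per
#'   undirected edge.
#' @export
as_tibble.area_graph <- function(x, ...) {
  from <- rep.int(seq_along(x$neighbours), lengths(x$neighbours))
  to <- unlist(x$neighbours, use.names = FALSE)
  keep <- from < to
  tibble::tibble(from = x$area_ids[from[keep]], to = x$area_ids[to[keep]])
}

#' Simulate an areal study region graph
#'
#' Generates a connected, symmetric planar adjacency structure standing in for
#' a real administrative map (for England's local authority districts that
#' would be 354 areas). Two layouts are available: a rook-adjacency rectangular
#' lattice, and a Gabriel graph of uniformly random points. The Gabriel graph
#' is planar and contains the Euclidean minimum spanning tree, so it is always
#' connected and has the irregular degree distribution of real administrative
#' adjacency.
#'
#' @param n_areas Number of areas (at least 2).
#' @param layout `"lattice"` (rook-adjacency grid, possibly with a partial
#'   last row) or `"random_planar"` (Gabriel graph of random points).
#' @param seed Integer seed; the result is a pure function of
#'   `(n_areas, layout, seed)`.
#' @return An [area_graph] with coordinates attached.
#' @examples
#' g <- simulate_area_graph(25, layout = "lattice", seed = 1)
#' lengths(g$neighbours)[1:5]
#' @export
simulate_area_graph <- function(n_areas, layout = c("lattice", "random_planar"),
                                seed = 1L) {
  layout <- match.arg(layout)
  if (!is.numeric(n_areas) || length(n_areas) != 1L || n_areas < 2) {
    stop("`n_areas` must be a single integer >= 2.", call. = FALSE)
  }
  n_areas <- as.integer(n_areas)
  if (layout == "lattice") {
    g <- lattice_graph(n_areas)
  } else {
    g <- withr::with_seed(as.integer(seed), gabriel_graph(n_areas))
  }
  g
}

lattice_graph <- function(n) {
  nr <- max(1L, floor(sqrt(n)))
  nc <- ceiling(n / nr)
  row <- (seq_len(n) - 1L) %/% nc + 1L
  col <- (seq_len(n) - 1L) %% nc + 1L
  nb <- vector("list", n)
  idx <- function(r, c) (r - 1L) * nc + c
  for (i in seq_len(n)) {
    cand <- c(
      if (col[i] > 1L) idx(row[i], col[i] - 1L),
      if (col[i] < nc) idx(row[i], col[i] + 1L),
      if (row[i] > 1L) idx(row[i] - 1L, col[i]),
      idx(row[i] + 1L, col[i])
    )
    nb[[i]] <- cand[cand <= n]
  }
  area_graph(nb, coords = cbind(x = col, y = -row))
}

# Gabriel graph: i~j iff no third point lies inside the circle with diameter ij
gabriel_graph <- function(n) {
  pts <- cbind(stats::runif(n), stats::runif(n))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      mid <- (pts[i, ] + pts[j, ]) / 2
      r2 <- sum((pts[i, ] - pts[j, ])^2) / 4
      d2 <- (pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2
      d2[c(i, j)] <- Inf
      if (all(d2 > r2)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  area_graph(nb, coords = pts)
}

#' Read a GAL neighbour-list file
#'
#' Parses the plain-text GAL dialect used by areal-analysis software: a header
#' line giving the number of areas, then for each area a line `"id n"`
#' followed by a line listing its `n` neighbour ids. Asymmetric adjacency is
#' rejected with the offending pair named.
#'
#' @param path Path to a GAL file.
#' @return An [area_graph].
#' @seealso [write_gal()]
#' @export
read_gal <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[[1L]], "\\s+")[[1L]]
  # GeoDa headers may carry leading 0 and dataset names; the count is the
  # first purely numeric token
  n <- as.integer(header[which(grepl("^[0-9]+$", header) & header != "0")[1L]])
  if (is.na(n)) stop("Cannot parse GAL header: ", lines[[1L]], call. = FALSE)
  ids <- character(n)
  raw_nb <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    head_k <- strsplit(lines[[pos]], "\\s+")[[1L]]
    ids[k] <- head_k[1L]
    n_nb <- as.integer(head_k[2L])
    if (n_nb > 0L) {
      raw_nb[[k]] <- strsplit(lines[[pos + 1L]], "\\s+")[[1L]]
      if (length(raw_nb[[k]]) != n_nb) {
        stop("Area ", ids[k], " announces ", n_nb, " neighbours but lists ",
             length(raw_nb[[k]]), ".", call. = FALSE)
      }
      pos <- pos + 2L
    } else {
      raw_nb[[k]] <- character(0)
      pos <- pos + 1L
    }
  }
  nb <- lapply(raw_nb, function(x) {
    m <- match(x, ids)
    if (anyNA(m)) stop("Unknown neighbour id: ", x[is.na(m)][1L], call. = FALSE)
    m
  })
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!i %in% nb[[j]]) {
        stop("Asymmetric adjacency in GAL file: ", ids[i], " ~ ", ids[j],
             " is not reciprocated.", call. = FALSE)
      }
    }
  }
  area_graph(nb, area_ids = ids)
}

#' Write an area graph to a GAL neighbour-list file
#'
#' @param g An [area_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_gal()]
#' @export
write_gal <- function(g, path) {
  stopifnot(inherits(g, "area_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(g$area_ids)), con)
  for (i in seq_along(g$area_ids)) {
    nb <- g$neighbours[[i]]
    writeLines(paste(g$area_ids[i], length(nb)), con)
    if (length(nb)) writeLines(paste(g$area_ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Export an area graph as GeoJSON
#'
#' Writes a GeoJSON `FeatureCollection` with one feature per area. Lattice
#' graphs get unit-square polygons around their grid coordinates; other graphs
#' get point features. Per-area properties can be attached from a data frame
#' keyed by `area_id`.
#'
#' @param g An [area_graph] with coordinates.
#' @param path Output path.
#' @param properties Optional data frame with an `area_id` column; remaining
#'   columns become feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(g, path, properties = NULL) {
  stopifnot(inherits(g, "area_graph"))
  if (is.null(g$coords)) stop("Graph carries no coordinates.", call. = FALSE)
  props <- lapply(seq_along(g$area_ids), function(i) {
    p <- list(area_id = g$area_ids[i])
    if (!is.null(properties)) {
      row <- properties[match(g$area_ids[i], properties$area_id), , drop = FALSE]
      extra <- row[setdiff(names(row), "area_id")]
      p <- c(p, lapply(as.list(extra), unname))
    }
    p
  })
  lattice_like <- all(g$coords == round(g$coords))
  feats <- lapply(seq_along(g$area_ids), function(i) {
    xy <- g$coords[i, ]
    geom <- if (lattice_like) {
      h <- 0.5
      ring <- list(c(xy[1] - h, xy[2] - h), c(xy[1] + h, xy[2] - h),
                   c(xy[1] + h, xy[2] + h), c(xy[1] - h, xy[2] + h),
                   c(xy[1] - h, xy[2] - h))
      list(type = "Polygon", coordinates = list(ring))
    } else {
      list(type = "Point", coordinates = c(xy[1], xy[2]))
    }
    list(type = "Feature", geometry = geom, properties = props[[i]])
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
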