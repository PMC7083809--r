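#' Triangulated surface mesh
#'
#' Container for a single triangulated tissue surface. Vertices are stored in
#' meters (file dialects use millimeters; conversion happens exactly once at
#' the read/write boundary) and triangle indices are 1-based.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in meters.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param name text label for the surface.
#' @return An object of class `surface_mesh` with fields `vertices`,
#'   `triangles`, `name`.
#' @export
surface_mesh <- function(vertices, triangles, name = "surface") {
  vertices <- as_points3(vertices, "vertices")
  triangles <- as.matrix(triangles)
  if (length(triangles) == 0L) {
    triangles <- matrix(integer(0), 0L, 3L)
  }
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  storage.mode(triangles) <- "integer"
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle index out of range [1, ", nrow(vertices), "]")
  structure(list(vertices = vertices, triangles = triangles,
                 name = as.character(name)[1]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d triangles, closed: %s\n",
              x$name, nrow(x$vertices), nrow(x$triangles),
              is_closed_surface(x)))
  invisible(x)
}

#' Check surface closedness
#'
#' A closed orientable surface has every edge shared by exactly two
#' triangles. Closedness is reported, never enforced: segmentations derived
#' from imaging data routinely contain imperfect surfaces and the mesher
#' tolerates them.
#'
#' @param mesh a [surface_mesh()].
#' @return `TRUE` if every edge occurs in exactly 2 triangles.
#' @export
is_closed_surface <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

#' Read a FreeSurfer ASCII surface (.ASC)
#'
#' The first non-comment line holds the vertex and face counts, followed by
#' one vertex per line (x y z in mm, optional trailing flag) and one face per
#' line (three 0-based vertex indices, optional trailing flag). Indices are
#' converted to 1-based, coordinates to meters.
#'
#' @param path path to the .ASC file.
#' @param name optional surface name; defaults to the file name.
#' @return A [surface_mesh()].
#' @export
read_freesurfer_asc <- function(path, name = NULL) {
  lines <- read_text_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop_parse(path, 1L, "no content lines")
  counts <- suppressWarnings(as.numeric(split_tokens(lines[idx[1]])))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop_parse(path, idx[1], "expected vertex and face counts")
  nv <- as.integer(counts[1]); nf <- as.integer(counts[2])
  if (length(idx) - 1L != nv + nf)
    stop_parse(path, idx[1],
               sprintf("declared %d vertices + %d faces but found %d lines",
                       nv, nf, length(idx) - 1L))
  parse_block <- function(rows, ncol_min, what) {
    out <- matrix(NA_real_, length(rows), ncol_min)
    for (i in seq_along(rows)) {
      tok <- suppressWarnings(as.numeric(split_tokens(lines[rows[i]])))
      if (length(tok) < ncol_min || anyNA(tok[seq_len(ncol_min)]))
        stop_parse(path, rows[i], paste("non-numeric", what, "line"))
      out[i, ] <- tok[seq_len(ncol_min)]
    }
    out
  }
  verts <- parse_block(idx[1L + seq_len(nv)], 3L, "vertex")
  tris <- if (nf > 0L) parse_block(idx[1L + nv + seq_len(nf)], 3L, "face")
          else matrix(numeric(0), 0L, 3L)
  tris <- tris + 1  # file is 0-based
  if (nf > 0L && (min(tris) < 1 || max(tris) > nv))
    stop_parse(path, idx[1L + nv + 1L], "face index out of range")
  surface_mesh(verts / 1000, tris,
               name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a FreeSurfer ASCII surface (.ASC)
#'
#' Inverse of [read_freesurfer_asc()]: coordinates written in millimeters at
#' full precision, face indices 0-based.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freesurfer_asc <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#!ascii surface '%s'", mesh$name), con)
  writeLines(sprintf("%d %d", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  v <- mesh$vertices * 1000
  writeLines(sprintf("%.17g %.17g %.17g 0", v[, 1], v[, 2], v[, 3]), con)
  t0 <- mesh$triangles - 1L
  if (nrow(t0) > 0L)
    writeLines(sprintf("%d %d %d 0", t0[, 1], t0[, 2], t0[, 3]), con)
  invisible(path)
}

#' Read a node/triangle .DAT file pair
#'
#' Nodes file: one `x y z` (mm) per line. Triangles file: one `i j k` per
#' line, 1-based.
#'
#' @param nodes_path,triangles_path paths to the two files.
#' @param name optional surface name.
#' @return A [surface_mesh()].
#' @export
read_dat_pair <- function(nodes_path, triangles_path, name = NULL) {
  nl <- read_text_lines(nodes_path)
  nl_keep <- which(nzchar(trimws(gsub("\r", "", nl))))
  verts <- matrix(NA_real_, length(nl_keep), 3L)
  for (i in seq_along(nl_keep)) {
    tok <- suppressWarnings(as.numeric(split_tokens(nl[nl_keep[i]])))
    if (length(tok) < 3L || anyNA(tok[1:3]))
      stop_parse(nodes_path, nl_keep[i], "expected x y z")
    verts[i, ] <- tok[1:3]
  }
  tl <- read_text_lines(triangles_path)
  tl_keep <- which(nzchar(trimws(gsub("\r", "", tl))))
  if (length(tl_keep) == 0L)
    warning("empty triangle file: ", triangles_path)
  tris <- matrix(integer(0), 0L, 3L)
  if (length(tl_keep) > 0L) {
    tris <- matrix(NA_integer_, length(tl_keep), 3L)
    for (i in seq_along(tl_keep)) {
      tok <- suppressWarnings(as.numeric(split_tokens(tl[tl_keep[i]])))
      if (length(tok) < 3L || anyNA(tok[1:3]))
        stop_parse(triangles_path, tl_keep[i], "expected i j k")
      if (any(tok[1:3] < 1) || any(tok[1:3] > nrow(verts)))
        stop_parse(triangles_path, tl_keep[i],
                   sprintf("node index out of range [1, %d]", nrow(verts)))
      tris[i, ] <- as.integer(tok[1:3])
    }
  }
  surface_mesh(verts / 1000, tris,
               name = name %||% sub("\\.[^.]*$", "", basename(nodes_path)))
}

#' Write a node/triangle .DAT pair
#'
#' @param mesh a [surface_mesh()].
#' @param nodes_path,triangles_path output paths.
#' @return invisibly, the two paths.
#' @export
write_dat_pair <- function(mesh, nodes_path, triangles_path) {
  v <- mesh$vertices * 1000
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), nodes_path)
  tr <- mesh$triangles
  writeLines(if (nrow(tr)) sprintf("%d %d %d", tr[, 1], tr[, 2], tr[, 3])
             else character(0), triangles_path)
  invisible(c(nodes_path, triangles_path))
}

#' Default tissue conductivities (S/m)
#'
#' White matter 0.14, grey matter 0.33, CSF 1.79, skull 0.0064, scalp 0.43.
#' The CSF value is the standard literature value; all defaults can be
#' overridden per compartment in the segmentation descriptor.
#'
#' @return Named numeric vector of conductivities in S/m.
#' @export
default_conductivities <- function() {
  c(white = 0.14, grey = 0.33, csf = 1.79, skull = 0.0064, scalp = 0.43)
}

lookup_default_conductivity <- function(name) {
  key <- tolower(name)
  tab <- default_conductivities()
  pats <- c(white = "white", grey = "gr[ae]y", csf = "csf|cerebro",
            skull = "skull|bone", scalp = "scalp|skin")
  for (k in names(pats)) if (grepl(pats[[k]], key)) return(tab[[k]])
  NA_real_
}

#' Build a segmentation from compartment descriptions
#'
#' A segmentation is an ordered (outermost-first) list of tissue
#' compartments, each holding one or more surface meshes (sub-meshes merged
#' under one label), a conductivity, a priority (lower value = higher
#' priority when an element's nodes straddle compartments) and an active
#' flag marking compartments that carry inverse-problem degrees of freedom.
#'
#' @param compartments list of lists with fields `name`, `sub_meshes` (list
#'   of [surface_mesh()]), `conductivity` (S/m), `priority`, `active`.
#' @return An object of class `segmentation`.
#' @export
segmentation <- function(compartments) {
  if (length(compartments) > 27L)
    stop("a head model can contain at most 27 tissue compartments, got ",
         length(compartments))
  for (cc in compartments) {
    if (!is.numeric(cc$conductivity) || cc$conductivity <= 0)
      stop("compartment '", cc$name, "' needs conductivity > 0")
    if (!length(cc$sub_meshes))
      stop("compartment '", cc$name, "' has no surface meshes")
  }
  structure(list(compartments = compartments), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation with %d compartments (outermost first):\n",
              length(x$compartments)))
  for (cc in x$compartments)
    cat(sprintf("  %-12s sigma=%g S/m priority=%d active=%s sub-meshes=%d\n",
                cc$name, cc$conductivity, cc$priority, cc$active,
                length(cc$sub_meshes)))
  invisible(x)
}

parse_ini <- function(path) {
  lines <- read_text_lines(path)
  lines <- gsub("\r", "", lines)
  secs <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(sub("[;#].*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      cur <- gsub("^\\[|\\]$", "", ln)
      secs[[cur]] <- list()
    } else if (grepl("=", ln)) {
      if (is.null(cur)) stop_parse(path, i, "key before any [section]")
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      secs[[cur]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else stop_parse(path, i, "expected [section] or key=value")
  }
  secs
}

#' Read a segmentation descriptor (.INI)
#'
#' One INI section per compartment, in outermost-first order. Recognised
#' keys: `files` (comma/semicolon-separated mesh paths, .ASC or
#' `nodes;triangles` .DAT pairs, relative to the INI file), `conductivity`
#' (S/m; falls back to [default_conductivities()] by compartment name),
#' `priority` (lower = higher; defaults give innermost compartments
#' priority), `active` (0/1).
#'
#' @param path path to the INI file.
#' @return A [segmentation()].
#' @export
read_segmentation_ini <- function(path) {
  secs <- parse_ini(path)
  if (length(secs) > 27L)
    stop("a head model can contain at most 27 tissue compartments, got ",
         length(secs))
  base <- dirname(path)
  n <- length(secs)
  comps <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- names(secs)[i]; s <- secs[[i]]
    files <- split_tokens(gsub(",", " ", s$files %||%
                                 stop("compartment '", nm, "' lists no files")))
    meshes <- list()
    j <- 1L
    while (j <= length(files)) {
      f <- file.path(base, files[j])
      if (!file.exists(f))
        stop("compartment '", nm, "': mesh file not found: ", f)
      if (grepl("\\.asc$", files[j], ignore.case = TRUE)) {
        meshes[[length(meshes) + 1L]] <- read_freesurfer_asc(f, name = nm)
        j <- j + 1L
      } else {
        if (j + 1L > length(files))
          stop("compartment '", nm, "': .DAT nodes file '", files[j],
               "' lacks its triangles file")
        f2 <- file.path(base, files[j + 1L])
        if (!file.exists(f2))
          stop("compartment '", nm, "': mesh file not found: ", f2)
        meshes[[length(meshes) + 1L]] <- read_dat_pair(f, f2, name = nm)
        j <- j + 2L
      }
    }
    cond <- if (!is.null(s$conductivity)) as.numeric(s$conductivity)
            else lookup_default_conductivity(nm)
    if (is.na(cond))
      stop("compartment '", nm,
           "' has no conductivity and no default matches its name")
    comps[[i]] <- list(
      name = nm, sub_meshes = meshes, conductivity = cond,
      # default: innermost (last section) gets the smallest value
      priority = if (!is.null(s$priority)) as.integer(s$priority)
                 else n - i + 1L,
      active = isTRUE(as.logical(s$active)) ||
        identical(s$active, "1"))
  }
  segmentation(comps)
}

#' Parcellation of points into labeled regions
#'
#' @param points numeric matrix, n x 3, in meters.
#' @param labels integer region id per point.
#' @param colortable named mapping region id -> region name (data.frame with
#'   columns `id`, `name`).
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(points, labels, colortable) {
  points <- as_points3(points)
  labels <- as.integer(labels)
  if (nrow(points) != length(labels))
    stop("points and labels lengths differ")
  orphan <- setdiff(unique(labels), colortable$id)
  if (length(orphan))
    stop("labels missing from colortable: ", paste(orphan, collapse = ", "))
  structure(list(points = points, labels = labels, colortable = colortable),
            class = "parcellation")
}

#' Read a parcellation from points/labels and colortable files
#'
#' The points file holds one point per line in annotation-ASCII layout:
#' either `x y z label` or `index x y z label` (mm). The colortable is
#' delimited text with columns `id` and `name`.
#'
#' @param points_path,colortable_path input paths.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(points_path, colortable_path) {
  lines <- read_text_lines(points_path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(gsub("\r", "", lines))))
  pts <- matrix(NA_real_, length(keep), 3L)
  labels <- integer(length(keep))
  for (i in seq_along(keep)) {
    tok <- suppressWarnings(as.numeric(split_tokens(lines[keep[i]])))
    if (length(tok) == 4L) {
      pts[i, ] <- tok[1:3]; labels[i] <- as.integer(tok[4])
    } else if (length(tok) >= 5L) {
      pts[i, ] <- tok[2:4]; labels[i] <- as.integer(tok[5])
    } else stop_parse(points_path, keep[i], "expected x y z label")
  }
  cl <- read_text_lines(colortable_path)
  cl <- cl[!grepl("^\\s*#", cl) & nzchar(trimws(gsub("\r", "", cl)))]
  ids <- integer(0); nms <- character(0)
  for (ln in cl) {
    tok <- split_tokens(ln)
    ids <- c(ids, as.integer(tok[1]))
    nms <- c(nms, tok[2])
  }
  parcellation(pts / 1000, labels,
               colortable = data.frame(id = ids, name = nms,
                                       stringsAsFactors = FALSE))
}

#' Save / load a project container
#'
#' A project is a named collection of any subset of the pipeline state
#' (mesh, lead field, sources, measurements, reconstruction, params),
#' persisted as a single versioned hierarchical binary file. Numeric arrays
#' round-trip bit-exactly.
#'
#' @param state named list of project fields.
#' @param path file path.
#' @return `save_project` returns `path` invisibly; `load_project` returns
#'   the state list.
#' @export
save_project <- function(state, path) {
  stopifnot(is.list(state))
  saveRDS(list(format = "neurofem_project", version = 1L, state = state),
          path)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "neurofem_project"))
    stop("not a neurofem project container: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported project container version: ", obj$version)
  obj$state
}
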