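#' @include AllClasses.R
NULL

# ---- hierarchy validation (shared by readers and the AtlasVolume class) ----

validateHierarchy <- function(h) {
  msg <- character()
  need <- c("id", "name", "parent_id", "r", "g", "b")
  if (!is.data.frame(h) || !all(need %in% names(h)))
    return(paste0("hierarchy must be a data.frame with columns ",
                  paste(need, collapse = ", ")))
  if (nrow(h) == 0L) return(character())
  if (any(is.na(h$id)) || any(h$id <= 0))
    msg <- c(msg, "hierarchy ids must be positive integers")
  if (anyDuplicated(h$id))
    msg <- c(msg, paste0("duplicate hierarchy ids: ",
                         paste(unique(h$id[duplicated(h$id)]), collapse = ", ")))
  bad <- !is.na(h$parent_id) & !(h$parent_id %in% h$id)
  if (any(bad))
    msg <- c(msg, paste0("unresolved parent ids: ",
                         paste(unique(h$parent_id[bad]), collapse = ", ")))
  if (length(msg) == 0L) {
    # cycle check: follow parent links from every node, bounded by node count
    parent <- h$parent_id[match(h$id, h$id)]
    names(parent) <- as.character(h$id)
    for (start in h$id) {
      cur <- start
      for (step in seq_len(nrow(h) + 1L)) {
        p <- parent[[as.character(cur)]]
        if (is.na(p)) break
        if (p == start || step > nrow(h)) {
          msg <- c(msg, paste0("cyclic parent links involving id ", start))
          break
        }
        cur <- p
      }
      if (length(msg)) break
    }
  }
  msg
}

emptyHierarchy <- function() {
  data.frame(id = integer(), name = character(), parent_id = integer(),
             r = integer(), g = integer(), b = integer(),
             stringsAsFactors = FALSE)
}

# ---- JSON I/O --------------------------------------------------------------

#' Read and write region hierarchy JSON
#'
#' The hierarchy file is a JSON document, either a bare array of region nodes
#' or an object \code{{"name", "voxel_size_um", "midline_axis",
#' "midline_coord", "regions": [...]}} whose metadata block describes the
#' atlas volume. Each region node is
#' \code{{"id", "name", "parent_id", "color": [r, g, b]}}; \code{parent_id}
#' is omitted (or \code{null}) for roots. \code{midline_axis} is 0-based in
#' the file. Writing then reading a hierarchy is value-identical.
#'
#' @param path File path.
#' @param hierarchy A hierarchy \code{data.frame}
#'   (columns \code{id, name, parent_id, r, g, b}).
#' @param metadata Optional list with entries \code{name},
#'   \code{voxel_size_um}, \code{midline_axis} (0-based), \code{midline_coord}
#'   to emit alongside the regions.
#' @return \code{readHierarchy} returns a list with elements \code{hierarchy}
#'   (the \code{data.frame}) and \code{metadata} (a list, possibly empty).
#'   \code{writeHierarchy} returns \code{path} invisibly.
#' @export
readHierarchy <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  meta <- list()
  nodes <- doc
  if (!is.null(names(doc)) && "regions" %in% names(doc)) {
    nodes <- doc$regions
    meta <- doc[setdiff(names(doc), "regions")]
  }
  if (length(nodes) == 0L) {
    h <- emptyHierarchy()
  } else {
    h <- do.call(rbind, lapply(nodes, function(n) {
      if (is.null(n$id) || is.null(n$name))
        stop("hierarchy node missing 'id' or 'name'", call. = FALSE)
      col <- if (is.null(n$color)) c(128L, 128L, 128L) else
        as.integer(unlist(n$color))
      data.frame(id = as.integer(n$id), name = as.character(n$name),
                 parent_id = if (is.null(n$parent_id)) NA_integer_ else
                   as.integer(n$parent_id),
                 r = col[1], g = col[2], b = col[3],
                 stringsAsFactors = FALSE)
    }))
  }
  msg <- validateHierarchy(h)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  list(hierarchy = h, metadata = meta)
}

#' @rdname readHierarchy
#' @export
writeHierarchy <- function(hierarchy, path, metadata = NULL) {
  msg <- validateHierarchy(hierarchy)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  nodes <- lapply(seq_len(nrow(hierarchy)), function(i) {
    n <- list(id = hierarchy$id[i], name = hierarchy$name[i])
    if (!is.na(hierarchy$parent_id[i])) n$parent_id <- hierarchy$parent_id[i]
    n$color <- c(hierarchy$r[i], hierarchy$g[i], hierarchy$b[i])
    n
  })
  doc <- if (is.null(metadata)) nodes else c(metadata, list(regions = nodes))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a volumetric label atlas
#'
#' Reads a 3D integer NIfTI label volume and its region hierarchy JSON into a
#' validated [AtlasVolume-class]. Voxel size is taken from the hierarchy
#' file's metadata block when present, else from the NIfTI pixdim. Midline
#' metadata (axis + plane coordinate) is declared in the metadata block, not
#' inferred; without it, hemisphere masking is unavailable.
#'
#' @param volumePath Path to a NIfTI-1 file with integer labels.
#' @param hierarchyPath Path to the hierarchy JSON (see [readHierarchy()]).
#' @param name Optional atlas name; overrides the metadata block.
#' @return An [AtlasVolume-class].
#' @examples
#' atl <- synthAtlas(seed = 1, dims = c(24, 32, 24), nNuclei = 1)
#' dir <- tempfile(); dir.create(dir)
#' writeAtlas(atl, file.path(dir, "atlas.nii.gz"), file.path(dir, "regions.json"))
#' atl2 <- readAtlas(file.path(dir, "atlas.nii.gz"), file.path(dir, "regions.json"))
#' atlasDims(atl2)
#' @export
readAtlas <- function(volumePath, hierarchyPath, name = NULL) {
  img <- RNifti::readNifti(volumePath)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]  # squeeze trailing singleton
  if (length(d) != 3L)
    stop("atlas volume must be 3D, got ", length(dim(img)), "D", call. = FALSE)
  vals <- as.vector(img)[seq_len(prod(d))]
  if (any(vals != floor(vals)))
    stop("atlas volume has non-integer voxel data", call. = FALSE)
  labels <- array(as.integer(vals), dim = d)
  hj <- readHierarchy(hierarchyPath)
  meta <- hj$metadata
  vox <- if (!is.null(meta$voxel_size_um)) as.numeric(unlist(meta$voxel_size_um))
    else {
      p <- RNifti::pixdim(img)[1:3]
      if (all(is.finite(p)) && all(p > 0)) p * 1000 else c(1, 1, 1)
    }
  if (length(vox) == 1L) vox <- rep(vox, 3)
  mlAxis <- if (!is.null(meta$midline_axis)) as.integer(meta$midline_axis) + 1L
    else NA_integer_
  mlCoord <- if (!is.null(meta$midline_coord)) as.numeric(meta$midline_coord)
    else NA_real_
  nm <- if (!is.null(name)) name else if (!is.null(meta$name)) meta$name
    else "atlas"
  new("AtlasVolume", name = nm, labels = labels, voxelSize = vox,
      midlineAxis = mlAxis, midlineCoord = mlCoord, hierarchy = hj$hierarchy)
}

#' Write an atlas volume and its hierarchy
#'
#' Writes the label grid as integer NIfTI and the hierarchy JSON with the
#' atlas metadata block, so that [readAtlas()] reproduces the object.
#'
#' @param atlas An [AtlasVolume-class].
#' @param volumePath Output NIfTI path (`.nii` or `.nii.gz`).
#' @param hierarchyPath Output hierarchy JSON path.
#' @return \code{volumePath}, invisibly.
#' @export
writeAtlas <- function(atlas, volumePath, hierarchyPath) {
  arr <- atlas@labels
  attr(arr, "pixdim") <- atlas@voxelSize / 1000   # mm
  img <- RNifti::asNifti(arr, datatype = "int32", internal = FALSE)
  RNifti::writeNifti(img, volumePath)
  meta <- list(name = atlas@name, voxel_size_um = atlas@voxelSize)
  if (!is.na(atlas@midlineAxis)) {
    meta$midline_axis <- atlas@midlineAxis - 1L
    meta$midline_coord <- atlas@midlineCoord
  }
  writeHierarchy(atlas@hierarchy, hierarchyPath, metadata = meta)
  invisible(volumePath)
}

# ---- hierarchy collapse ----------------------------------------------------

ancestorChain <- function(hierarchy, id) {
  # ancestors from self up to root (inclusive of self)
  chain <- integer()
  cur <- id
  parent <- hierarchy$parent_id[match(hierarchy$id, hierarchy$id)]
  repeat {
    chain <- c(chain, cur)
    p <- hierarchy$parent_id[match(cur, hierarchy$id)]
    if (is.na(p)) break
    cur <- p
  }
  chain
}

#' Collapse the region hierarchy to reporting regions
#'
#' Maps every hierarchy node id to its nearest selected ancestor-or-self
#' ("parent region"); nodes with no selected ancestor map to 0 and are
#' treated as background by quantification and QC. Selecting nested ids is
#' ambiguous and raises an error.
#'
#' @param hierarchy Hierarchy \code{data.frame} or an [AtlasVolume-class].
#' @param selectedIds Integer vector of reporting region ids
#'   (subset of hierarchy ids; empty selection maps everything to 0).
#' @return A named integer vector: names are all hierarchy ids, values the
#'   reporting id each maps to (0 = unselected).
#' @examples
#' atl <- synthAtlas(seed = 1, dims = c(24, 32, 24), nNuclei = 1)
#' h <- regionHierarchy(atl)
#' # report at hemisphere level
#' m <- collapseHierarchy(h, h$id[is.na(h$parent_id) == FALSE & h$parent_id == 1])
#' table(m)
#' @export
collapseHierarchy <- function(hierarchy, selectedIds) {
  if (is(hierarchy, "AtlasVolume")) hierarchy <- hierarchy@hierarchy
  msg <- validateHierarchy(hierarchy)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  selectedIds <- as.integer(selectedIds)
  if (anyDuplicated(selectedIds))
    selectedIds <- unique(selectedIds)
  bad <- setdiff(selectedIds, hierarchy$id)
  if (length(bad))
    stop("selected ids not in hierarchy: ", paste(bad, collapse = ", "),
         call. = FALSE)
  # nested selection check: no selected id may have a selected proper ancestor
  for (id in selectedIds) {
    anc <- ancestorChain(hierarchy, id)
    hit <- intersect(anc[-1], selectedIds)
    if (length(hit))
      stop("nested selection: id ", id, " descends from selected id ",
           hit[1], call. = FALSE)
  }
  mapping <- integer(nrow(hierarchy))
  names(mapping) <- as.character(hierarchy$id)
  for (i in seq_len(nrow(hierarchy))) {
    anc <- ancestorChain(hierarchy, hierarchy$id[i])
    hit <- anc[anc %in% selectedIds]
    mapping[i] <- if (length(hit)) hit[1] else 0L
  }
  mapping
}

# Apply a RegionMapping to a label matrix/array; labels absent from the
# mapping (only background 0 in validated atlases) map to 0.
applyMapping <- function(labels, mapping) {
  ids <- as.integer(names(mapping))
  idx <- match(labels, ids)
  out <- ifelse(is.na(idx), 0L, as.integer(mapping)[idx])
  if (is.matrix(labels)) dim(out) <- dim(labels)
  out
}

regionName <- function(hierarchy, ids) {
  nm <- hierarchy$name[match(ids, hierarchy$id)]
  nm[ids == 0L] <- "background"
  nm[is.na(nm)] <- "unknown"
  nm
}

# Stable fingerprint of a mapping, used to refuse aggregation across mappings.
mappingKey <- function(mapping) {
  if (is.null(mapping)) return("identity")
  o <- order(as.integer(names(mapping)))
  paste(names(mapping)[o], as.integer(mapping)[o], sep = ":", collapse = ",")
}
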