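#' Write a cohort to disk as tab-separated time-series files plus a manifest
#'
#' One file per subject-by-condition run (frames in rows, nodes in columns,
#' header `node_1..node_K`), and a comma-separated manifest with columns
#' subject_id, group, condition, path, seed.
#'
#' @param cohort a [CohortTimeSeries-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- subjects(cohort)
  rows <- list()
  for (s in seq_len(nrow(sub))) {
    for (cond in names(cohort@frames)) {
      key <- paste(sub$id[s], cond, sep = ".")
      path <- file.path(dir, sprintf("sub-%s_%s.tsv", sub$id[s], cond))
      write.table(cohort@series[[key]], path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      rows[[key]] <- data.frame(subject_id = sub$id[s], group = sub$group[s],
                                condition = cond, path = basename(path),
                                seed = unname(cohort@runSeeds[key]))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `manifest.csv` and the per-run TSV files.
#' @return a [CohortTimeSeries-class].
#' @export
readCohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  ids <- unique(manifest$subject_id)
  grp <- manifest$group[match(ids, manifest$subject_id)]
  series <- list()
  frames <- integer(0)
  runSeeds <- integer(0)
  for (r in seq_len(nrow(manifest))) {
    m <- as.matrix(read.table(file.path(dir, manifest$path[r]), header = TRUE,
                              sep = "\t"))
    key <- paste(manifest$subject_id[r], manifest$condition[r], sep = ".")
    series[[key]] <- m
    frames[manifest$condition[r]] <- nrow(m)
    runSeeds[key] <- manifest$seed[r]
  }
  new("CohortTimeSeries",
      subjects = DataFrame(id = ids, group = grp),
      series = series, frames = frames,
      nNodes = ncol(series[[1]]),
      seed = NA_integer_, runSeeds = runSeeds)
}

# pad a V x n matrix into a 4D array on the toy voxel grid
.toGrid <- function(m, gridDim) {
  flat <- matrix(0, prod(gridDim), ncol(m))
  flat[seq_len(nrow(m)), ] <- m
  array(flat, dim = c(gridDim, ncol(m)))
}

#' Write a toy volume set as NIfTI files
#'
#' Voxels are arranged in a small 3D grid (zero-padded); writes one 4D
#' image per run, a 4D map stack, and a 3D binary lesion mask.
#'
#' @param tvs a [ToyVolumeSet-class].
#' @param dir output directory.
#' @return invisibly, the vector of file paths written.
#' @export
writeToyVolumes <- function(tvs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  g <- tvs@gridDim
  p <- file.path(dir, "maps.nii.gz")
  RNifti::writeNifti(.toGrid(tvs@maps, g), p)
  paths <- c(paths, p)
  p <- file.path(dir, "lesion_mask.nii.gz")
  RNifti::writeNifti(array(c(tvs@lesionMask,
                             rep(0, prod(g) - length(tvs@lesionMask))),
                           dim = g), p)
  paths <- c(paths, p)
  for (key in names(tvs@volumes)) {
    p <- file.path(dir, sprintf("vol-%s.nii.gz", gsub("\\.", "_", key)))
    RNifti::writeNifti(.toGrid(tvs@volumes[[key]], g), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a 4D NIfTI image as a voxel-by-time matrix
#'
#' @param path NIfTI file.
#' @param nVoxels optional number of leading voxels to keep (toy grids are
#'   zero-padded).
#' @return V x T matrix.
#' @export
readVolumeMatrix <- function(path, nVoxels = NULL) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1)
  m <- matrix(a, prod(dim(a)[1:3]), dim(a)[4])
  if (!is.null(nVoxels)) m <- m[seq_len(nVoxels), , drop = FALSE]
  m
}

#' Read a motion-parameter trace
#'
#' Six whitespace-delimited columns, one row per frame: three rotations
#' (radians) then three translations (mm), the ordering used by the usual
#' realignment tools.
#'
#' @param path text file.
#' @return F x 6 matrix.
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion trace must have 6 columns")
  colnames(m) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  m
}
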