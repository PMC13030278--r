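#' Registry of the 19 named imaging features
#'
#' The fixed feature registry: 19 named features grouped as morphological
#' (6), intensity-based (4), texture (7) and anatomical/tract (2). Some
#' named features are multi-component (centroid expands to 3 scalars,
#' quadrant distribution to 4, CST volume and CST overlap to 2 each), so
#' the vectorized design matrix has 26 columns with a fixed documented
#' order.
#'
#' @return data.frame with columns \code{feature}, \code{group},
#'   \code{width} and \code{columns} (comma-separated expanded column
#'   names).
#' @export
featureRegistry <- function() {
  reg <- list(
    list("volume",                "morphological", "volume_ml"),
    list("surface_area",          "morphological", "surface_area_mm2"),
    list("sphericity",            "morphological", "sphericity"),
    list("solidity",              "morphological", "solidity"),
    list("elongation",            "morphological", "elongation"),
    list("compactness",           "morphological", "compactness"),
    list("max_intensity",         "intensity", "max_intensity"),
    list("avg_intensity",         "intensity", "avg_intensity"),
    list("centroid",              "intensity",
         c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")),
    list("quadrant_distribution", "intensity",
         c("quadrant_la", "quadrant_lp", "quadrant_ra", "quadrant_rp")),
    list("contrast",              "texture", "contrast"),
    list("dissimilarity",         "texture", "dissimilarity"),
    list("homogeneity",           "texture", "homogeneity"),
    list("asm",                   "texture", "asm"),
    list("energy",                "texture", "energy"),
    list("correlation",           "texture", "correlation"),
    list("entropy",               "texture", "entropy"),
    list("cst_volume",            "tract",
         c("cst_left_volume_ml", "cst_right_volume_ml")),
    list("cst_overlap",           "tract",
         c("cst_left_overlap_pct", "cst_right_overlap_pct")))
  data.frame(
    feature = vapply(reg, `[[`, "", 1L),
    group = vapply(reg, `[[`, "", 2L),
    width = vapply(reg, function(r) length(r[[3L]]), 0L),
    columns = vapply(reg, function(r) paste(r[[3L]], collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Expanded feature column names, in design-matrix order
#' @return character vector of the 26 vectorized feature columns.
#' @export
featureColumns <- function() {
  unlist(strsplit(featureRegistry()$columns, ","), use.names = FALSE)
}

#' Extraction configuration
#'
#' Bundles the tunable settings of the feature-extraction stages. The
#' configuration hash stamps every cohort table produced with it so that
#' tables extracted under different settings refuse to combine.
#'
#' @param quadrant a [quadrantConfig()].
#' @param glcm a [glcmConfig()].
#' @param surfaceSigma surface anti-aliasing bandwidth in voxels, see
#'   [surfaceArea()].
#' @param maskThreshold binarization threshold for probabilistic masks.
#' @return a list with class "extractionConfig".
#' @export
extractionConfig <- function(quadrant = quadrantConfig(),
                             glcm = glcmConfig(), surfaceSigma = 1.25,
                             maskThreshold = 0.5) {
  cfg <- structure(list(quadrant = quadrant, glcm = glcm,
                        surfaceSigma = surfaceSigma,
                        maskThreshold = maskThreshold),
                   class = "extractionConfig")
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' @rdname extractionConfig
#' @param config an extractionConfig.
#' @export
configHash <- function(config) {
  h <- attr(config, "hash")
  if (!is.null(h)) return(h)
  f <- tempfile()
  on.exit(unlink(f))
  x <- unclass(config)
  attributes(x) <- list(names = names(x))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.pkgVersion <- function() {
  as.character(utils::packageVersion("strokemark"))
}

#' Extract the full feature record of one subject
#'
#' Fuses the candidate lesion masks by [majorityVote()], then computes all
#' 19 named features (26 vectorized columns): morphology, spatial and
#' intensity descriptors, slice-wise GLCM texture, and CST overlap
#' metrics. Stage failures never abort: an empty fused lesion yields
#' volume 0 with NA shape/intensity/texture features and 0\% overlaps
#' (with a warning), and any other stage error yields NA for that stage's
#' columns.
#'
#' @param subjectId subject identifier string.
#' @param adc the subject's ADC [ScalarVolume-class].
#' @param lesionCandidates list of candidate lesion [BinaryMask-class]es
#'   (one per segmentation model).
#' @param cstLeft,cstRight CST [BinaryMask-class]es.
#' @param config an [extractionConfig()].
#' @return one-row data.frame: \code{subject_id} plus the 26 registry
#'   columns, with the configuration hash and package version as
#'   attributes.
#' @export
extractSubject <- function(subjectId, adc, lesionCandidates, cstLeft,
                           cstRight, config = extractionConfig()) {
  lesion <- majorityVote(lesionCandidates)
  cols <- featureColumns()
  rec <- as.list(stats::setNames(rep(NA_real_, length(cols)), cols))
  rec$volume_ml <- lesionVolume(lesion)
  stage <- function(expr) tryCatch(expr, error = function(e) {
    warning("subject ", subjectId, ": ", conditionMessage(e), call. = FALSE)
    NULL
  })
  if (voxelCount(lesion) > 0L) {
    m <- stage(morphologyFeatures(lesion, sigma = config$surfaceSigma))
    if (!is.null(m)) {
      rec$surface_area_mm2 <- m$surface_area_mm2
      rec$sphericity <- m$sphericity
      rec$solidity <- m$solidity
      rec$elongation <- m$elongation
      rec$compactness <- m$compactness
    }
    s <- stage(spatialIntensityFeatures(adc, lesion, config$quadrant))
    if (!is.null(s)) {
      rec$centroid_x_mm <- s$centroid_world_mm[1]
      rec$centroid_y_mm <- s$centroid_world_mm[2]
      rec$centroid_z_mm <- s$centroid_world_mm[3]
      rec$max_intensity <- s$max_intensity
      rec$avg_intensity <- s$avg_intensity
      rec$quadrant_la <- s$quadrants[["LA"]]
      rec$quadrant_lp <- s$quadrants[["LP"]]
      rec$quadrant_ra <- s$quadrants[["RA"]]
      rec$quadrant_rp <- s$quadrants[["RP"]]
    }
    tx <- stage(lesionTexture(adc, lesion, config$glcm))
    if (!is.null(tx)) {
      rec$contrast <- tx[["contrast"]]
      rec$dissimilarity <- tx[["dissimilarity"]]
      rec$homogeneity <- tx[["homogeneity"]]
      rec$asm <- tx[["asm"]]
      rec$energy <- tx[["energy"]]
      rec$correlation <- tx[["correlation"]]
      rec$entropy <- tx[["entropy"]]
    }
  } else {
    warning("subject ", subjectId, ": empty fused lesion; shape/intensity/",
            "texture features set to NA", call. = FALSE)
  }
  ov <- stage(overlapMetrics(lesion, cstLeft, cstRight))
  if (!is.null(ov)) {
    rec$cst_left_volume_ml <- ov$left_cst_volume_ml
    rec$cst_right_volume_ml <- ov$right_cst_volume_ml
    rec$cst_left_overlap_pct <- ov$left_overlap_pct
    rec$cst_right_overlap_pct <- ov$right_overlap_pct
  }
  out <- as.data.frame(t(unlist(rec)))
  out <- cbind(data.frame(subject_id = subjectId, stringsAsFactors = FALSE),
               out)
  attr(out, "configHash") <- configHash(config)
  attr(out, "version") <- .pkgVersion()
  out
}

#' Assemble subject records into a CohortTable
#'
#' @param records a list of one-row data.frames from [extractSubject()]
#'   (or one already-bound data.frame with a subject_id column).
#' @param config the [extractionConfig()] the records were produced with.
#' @return a [CohortTable-class].
#' @export
makeCohortTable <- function(records, config = extractionConfig()) {
  df <- if (is.data.frame(records)) records else do.call(rbind, records)
  rownames(df) <- NULL
  attr(df, "configHash") <- NULL
  attr(df, "version") <- NULL
  new("CohortTable", features = df, configHash = configHash(config),
      version = .pkgVersion())
}

#' Combine cohort tables extracted under the same configuration
#'
#' Tables whose configuration hashes differ refuse to concatenate, since
#' their feature values are not comparable.
#'
#' @param ... [CohortTable-class] objects.
#' @return a single [CohortTable-class].
#' @export
combineCohorts <- function(...) {
  tabs <- list(...)
  h <- vapply(tabs, function(t) t@configHash, "")
  if (length(unique(h)) > 1L)
    stop("cannot combine cohort tables with different configuration hashes")
  new("CohortTable", features = do.call(rbind, lapply(tabs, function(t) t@features)),
      configHash = h[1], version = tabs[[1]]@version)
}

#' Attach outcome labels to a cohort table
#'
#' Joins a subject_id -> mRS table (modified Rankin Scale, integer 0--6)
#' onto the cohort. Rows without a label are flagged as excluded from
#' outcome modelling; the binary outcome is derived as unfavourable
#' (\code{outcome = 1}) when mRS > 2 and favourable (\code{outcome = 0})
#' when mRS <= 2. Label file entries whose subject ids are not in the
#' cohort are ignored with a warning.
#'
#' @param table a [CohortTable-class].
#' @param labels data.frame with columns \code{subject_id} and \code{mrs},
#'   or the path of a CSV file with those columns.
#' @return the table with \code{mrs}, \code{outcome} and \code{labeled}
#'   columns filled in.
#' @export
attachLabels <- function(table, labels) {
  stopifnot(is(table, "CohortTable"))
  if (is.character(labels)) labels <- utils::read.csv(labels)
  stopifnot(all(c("subject_id", "mrs") %in% names(labels)))
  unknown <- setdiff(labels$subject_id, table@features$subject_id)
  if (length(unknown))
    warning(length(unknown), " label entries with unknown subject ids ignored")
  f <- table@features
  i <- match(f$subject_id, labels$subject_id)
  f$mrs <- as.integer(labels$mrs[i])
  f$labeled <- !is.na(f$mrs)
  f$outcome <- ifelse(f$labeled, as.integer(f$mrs > 2L), NA_integer_)
  nExcl <- sum(!f$labeled)
  if (nExcl > 0L)
    message(nExcl, " of ", nrow(f),
            " subjects lack an mRS label and are excluded from outcome modelling")
  methods::initialize(table, features = f)
}

#' Write / read a cohort table as CSV
#'
#' The CSV has a fixed documented column order (subject_id, the 26 registry
#' columns, then any label columns); the first line is a comment carrying
#' the configuration hash and package version so a round trip is lossless.
#' NA cells serialize as empty fields.
#'
#' @param table a [CohortTable-class].
#' @param path output / input CSV path.
#' @return \code{writeCohort}: \code{path} invisibly; \code{readCohort}:
#'   a [CohortTable-class].
#' @export
writeCohort <- function(table, path) {
  stopifnot(is(table, "CohortTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strokemark cohort configHash=%s version=%s",
                     table@configHash, table@version), con)
  utils::write.csv(table@features, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  head1 <- readLines(path, n = 1L)
  m <- regmatches(head1,
    regexec("^# strokemark cohort configHash=([0-9a-f]+) version=(\\S+)", head1))[[1]]
  if (length(m) != 3L)
    stop("parse error at line 1 of ", path, ": not a cohort CSV header")
  f <- tryCatch(utils::read.csv(path, comment.char = "#", na.strings = ""),
                error = function(e)
                  stop("parse error in ", path, ": ", conditionMessage(e)))
  need <- c("subject_id", featureColumns())
  miss <- setdiff(need, names(f))
  if (length(miss))
    stop("parse error in ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  f$subject_id <- as.character(f$subject_id)
  if ("labeled" %in% names(f)) f$labeled <- as.logical(f$labeled)
  new("CohortTable", features = f, configHash = m[2], version = m[3])
}

#' Batch-extract a cohort from a manifest file
#'
#' The manifest is a CSV with columns \code{subject_id}, \code{adc},
#' \code{lesions} (one or more candidate mask paths separated by
#' semicolons), \code{cst_left} and \code{cst_right}. Each subject is
#' loaded, extracted with [extractSubject()] and bound into a
#' [CohortTable-class]; per-subject failures yield an NA-flagged row and a
#' warning, never an abort.
#'
#' @param manifest path to the manifest CSV.
#' @param config an [extractionConfig()].
#' @param labels optional path of a subject_id -> mrs CSV, passed to
#'   [attachLabels()].
#' @return a [CohortTable-class].
#' @export
cohortFromManifest <- function(manifest, config = extractionConfig(),
                               labels = NULL) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "adc", "lesions", "cst_left", "cst_right")
  stopifnot(all(need %in% names(man)))
  recs <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    tryCatch({
      adc <- loadVolume(row$adc, takeFirstOf4D = TRUE)
      cand <- lapply(strsplit(row$lesions, ";")[[1]], loadMask,
                     threshold = config$maskThreshold)
      extractSubject(row$subject_id, adc, cand,
                     loadMask(row$cst_left), loadMask(row$cst_right), config)
    }, error = function(e) {
      warning("subject ", row$subject_id, " failed: ", conditionMessage(e),
              call. = FALSE)
      out <- data.frame(subject_id = row$subject_id)
      for (cl in featureColumns()) out[[cl]] <- NA_real_
      out
    })
  })
  tab <- makeCohortTable(recs, config)
  if (!is.null(labels)) tab <- attachLabels(tab, labels) else tab
}
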