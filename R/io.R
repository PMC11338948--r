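# File formats: PNG mask channels, landmark annotations (JSON/CSV/CVAT
# points XML), pixel spacing (config value or DICOM metadata), classifier
# scores, and report/manifest output. All serialized pixel coordinates are
# 0-based.

.KNOWN_LANDMARKS <- c("carina", "cavoatrial_junction", "ge_junction",
                      "t1_level", "aortic_arch_upper")

#' Write mask channels as PNG files
#'
#' One single-channel PNG per mask channel, named
#' `<imageId>_<channel>.png`, with foreground stored as white (255).
#'
#' @param masks a [MaskChannelSet-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
writeMaskChannels <- function(masks, dir) {
  stopifnot(is(masks, "MaskChannelSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(masks@channels)) {
    p <- file.path(dir, paste0(masks@meta@imageId, "_", nm, ".png"))
    png::writePNG(masks@channels[[nm]] + 0.0, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read mask channels from PNG files
#'
#' Reads `<imageId>_<channel>.png` for the four channels; intensities at or
#' above 0.5 are foreground. A missing channel file yields an all-zero
#' channel (tube absent); it is an error when no channel file exists at all.
#'
#' @param dir directory holding the PNGs
#' @param imageId image identifier (file-name prefix)
#' @param meta an [ImageMeta-class] giving size and spacing
#' @return a [MaskChannelSet-class]
#' @export
readMaskChannels <- function(dir, imageId, meta) {
  found <- FALSE
  get <- function(nm) {
    p <- file.path(dir, paste0(imageId, "_", nm, ".png"))
    if (!file.exists(p)) return(NULL)
    found <<- TRUE
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.integer(img >= 0.5), nrow(img), ncol(img))
  }
  chans <- lapply(stats::setNames(.MASK_CHANNELS, .MASK_CHANNELS), get)
  if (!found)
    stop("no mask channel files for image '", imageId, "' under ", dir)
  MaskChannelSet(meta, ngtLine = chans$ngt_line, cvcLine = chans$cvc_line,
                 cvcTip = chans$cvc_tip, ettTip = chans$ett_tip)
}

.lmFromRecords <- function(df, src) {
  need <- c("image_id", "name", "x", "y")
  if (!all(need %in% names(df)))
    stop(src, " must provide columns/fields: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$name), .KNOWN_LANDMARKS)
  if (length(bad))
    stop("unknown landmark name(s) in ", src, ": ", paste(bad, collapse = ", "))
  out <- list()
  for (id in unique(df$image_id)) {
    rows <- df[df$image_id == id, , drop = FALSE]
    if (anyDuplicated(rows$name))
      stop("duplicate landmark '", rows$name[duplicated(rows$name)][1],
           "' for image '", id, "'")
    g <- function(nm) {
      r <- rows[rows$name == nm, , drop = FALSE]
      if (nrow(r)) c(r$x[1], r$y[1]) else NULL
    }
    out[[id]] <- LandmarkSet(
      carina = g("carina"), cavoatrialJunction = g("cavoatrial_junction"),
      geJunction = g("ge_junction"),
      t1LevelY = { r <- g("t1_level"); if (is.null(r)) NULL else r[2] },
      aorticArchUpperY = { r <- g("aortic_arch_upper"); if (is.null(r)) NULL else r[2] }
    )
  }
  out
}

#' Read landmark annotations (JSON or CSV)
#'
#' JSON: an array of records `{image_id, name, x, y}`. CSV: columns
#' `image_id,name,x,y`. Coordinates are 0-based pixels. Known landmark names
#' are `carina`, `cavoatrial_junction`, `ge_junction`, `t1_level`,
#' `aortic_arch_upper`; anything else is rejected by name, and a duplicated
#' landmark for one image is an error naming that image.
#'
#' @param path file path (`.json` or `.csv` by extension)
#' @return named list of [LandmarkSet-class], keyed by image id (empty list
#'   for an empty file)
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0L) return(list())
    as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    if (length(readLines(path, n = 1L)) == 0L) return(list())
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  .lmFromRecords(df, path)
}

#' Write landmark annotations to JSON
#'
#' @param landmarks named list of [LandmarkSet-class] keyed by image id
#' @param path output path
#' @export
writeLandmarks <- function(landmarks, path) {
  recs <- list()
  for (id in names(landmarks)) {
    lm <- landmarks[[id]]
    for (nm in names(lm@points)) {
      p <- lm@points[[nm]]
      recs[[length(recs) + 1L]] <-
        list(image_id = id, name = nm, x = p[[1]], y = p[[2]])
    }
    if (length(lm@t1LevelY))
      recs[[length(recs) + 1L]] <-
        list(image_id = id, name = "t1_level", x = 0, y = lm@t1LevelY)
    if (length(lm@aorticArchUpperY))
      recs[[length(recs) + 1L]] <-
        list(image_id = id, name = "aortic_arch_upper", x = 0, y = lm@aorticArchUpperY)
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default CVAT label aliases
#'
#' Maps the free-text point labels used in the annotation tool to the
#' package's landmark names.
#' @format named character vector
#' @export
CVAT_DEFAULT_ALIASES <- c(
  "carina" = "carina",
  "cavoatrial junction" = "cavoatrial_junction",
  "cavoatrial_junction" = "cavoatrial_junction",
  "gastroesophageal junction" = "ge_junction",
  "ge junction" = "ge_junction",
  "ge_junction" = "ge_junction"
)

#' Import landmarks from CVAT 1.1 "points" XML
#'
#' Reads `<image>` elements and their `<points>` children; the point label is
#' mapped through the alias table, unknown labels are an error naming the
#' label. CVAT exports 0-based floating-point coordinates, which are kept
#' as-is (the package convention is also 0-based).
#'
#' @param path CVAT 1.1 annotation XML
#' @param aliases named character vector mapping CVAT labels to landmark
#'   names (default [CVAT_DEFAULT_ALIASES])
#' @return named list of [LandmarkSet-class] keyed by image name (sans
#'   extension)
#' @export
readCvatPoints <- function(path, aliases = CVAT_DEFAULT_ALIASES) {
  doc <- xml2::read_xml(path)
  imgs <- xml2::xml_find_all(doc, ".//image")
  recs <- list()
  for (img in imgs) {
    id <- tools::file_path_sans_ext(xml2::xml_attr(img, "name"))
    for (pt in xml2::xml_find_all(img, "./points")) {
      lab <- xml2::xml_attr(pt, "label")
      mapped <- unname(aliases[tolower(lab)])
      if (is.na(mapped) || is.null(mapped))
        stop("CVAT label '", lab, "' has no alias mapping to a landmark name")
      xy <- as.numeric(strsplit(strsplit(xml2::xml_attr(pt, "points"), ";")[[1]][1],
                                ",")[[1]])
      if (length(xy) != 2L || anyNA(xy))
        stop("malformed points attribute for label '", lab, "' in image '", id, "'")
      recs[[length(recs) + 1L]] <-
        data.frame(image_id = id, name = mapped, x = xy[1], y = xy[2],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(list())
  .lmFromRecords(do.call(rbind, recs), path)
}

# --- pixel spacing ----------------------------------------------------------

# Minimal DICOM tag scanner for pixel spacing. Supports explicit-VR
# little-endian files (preamble + "DICM"); written in-package because no
# installed R package reads DICOM.
.readDicomPixelSpacing <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  spacing <- c(PixelSpacing = NA_character_, ImagerPixelSpacing = NA_character_)
  repeat {
    group <- u16()
    if (!length(group)) break
    elem <- u16()
    vr <- rawToChar(readBin(con, "raw", 2L))
    if (vr %in% long_vrs) {
      readBin(con, "raw", 2L)
      len <- u32()
    } else {
      len <- u16()
    }
    if (group == 0x7FE0) break           # pixel data: nothing of interest beyond
    if (len < 0 || !length(len)) break
    val <- readBin(con, "raw", len)
    tag <- sprintf("%04X%04X", group, elem)
    if (tag == "00280030") spacing["PixelSpacing"] <- rawToChar(val)
    if (tag == "00181164") spacing["ImagerPixelSpacing"] <- rawToChar(val)
    if (!is.na(spacing["PixelSpacing"])) break
  }
  raw <- if (!is.na(spacing["PixelSpacing"])) spacing["PixelSpacing"]
         else spacing["ImagerPixelSpacing"]
  if (is.na(raw))
    stop("no PixelSpacing/ImagerPixelSpacing attribute in ", path)
  v <- as.numeric(strsplit(trimws(raw), "\\\\")[[1]])
  if (length(v) == 1L) v <- c(v, v)
  if (length(v) != 2L || anyNA(v) || any(v <= 0))
    stop("malformed pixel spacing value in ", path, ": '", raw, "'")
  c(row = v[1], col = v[2])               # DICOM stores row spacing first
}

#' Resolve pixel spacing from DICOM metadata or a configured value
#'
#' DICOM `PixelSpacing` (or `ImagerPixelSpacing`) takes precedence over a
#' configured value; when both are available and disagree by more than 1%, a
#' warning is emitted and the DICOM value wins. A missing spacing is a hard
#' error: the position rules are centimetre-denominated and cannot run
#' without a metric scale.
#'
#' @param dicomPath optional path to a DICOM file (explicit-VR little-endian)
#' @param configSpacing optional numeric spacing: one value (isotropic) or
#'   `c(row, col)` mm/px
#' @return named numeric `c(row, col)` in mm/px, with attribute `"source"`
#'   (`"dicom"` or `"config"`)
#' @export
readSpacing <- function(dicomPath = NULL, configSpacing = NULL) {
  fromCfg <- NULL
  if (!is.null(configSpacing)) {
    v <- as.numeric(configSpacing)
    if (length(v) == 1L) v <- c(v, v)
    if (length(v) != 2L || anyNA(v) || any(v <= 0))
      stop("configSpacing must be one or two positive numbers (mm/px)")
    fromCfg <- c(row = v[1], col = v[2])
  }
  fromDcm <- if (!is.null(dicomPath)) .readDicomPixelSpacing(dicomPath)
  if (is.null(fromDcm) && is.null(fromCfg))
    stop("pixel spacing unavailable: supply a DICOM file or a configured value; ",
         "metric position rules cannot run without it")
  if (!is.null(fromDcm) && !is.null(fromCfg) &&
      any(abs(fromDcm - fromCfg) / fromCfg > 0.01))
    warning("DICOM pixel spacing (", paste(fromDcm, collapse = "\\"),
            ") disagrees with configured spacing (",
            paste(fromCfg, collapse = "\\"), ") by more than 1%; using DICOM")
  out <- fromDcm %||% fromCfg
  attr(out, "source") <- if (is.null(fromDcm)) "config" else "dicom"
  out
}

# --- scores -----------------------------------------------------------------

#' Read per-image classifier scores
#'
#' JSON-lines (one object per line with `image_id` plus the 11 label fields)
#' or CSV with an `image_id` column.
#'
#' @param path input path (`.jsonl`/`.json` or `.csv`)
#' @return numeric matrix over [RANZCR_LABELS] with image ids as row names
#' @export
readClassScores <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("jsonl", "json")) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  miss <- setdiff(c("image_id", RANZCR_LABELS), names(df))
  if (length(miss)) stop("score file missing field(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, RANZCR_LABELS])
  rownames(m) <- df$image_id
  m
}

#' Write per-image classifier scores as JSON-lines
#'
#' @param scores matrix over [RANZCR_LABELS] with image-id row names
#' @param path output path
#' @export
writeClassScores <- function(scores, path) {
  sm <- .scoresMatrix(scores)
  ids <- rownames(sm) %||% as.character(seq_len(nrow(sm)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sm))) {
    rec <- c(list(image_id = ids[i]), as.list(sm[i, ]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

# --- decisions and reports --------------------------------------------------

#' Write per-image rule decisions
#'
#' JSON-lines with one record per image (tips, distances, fired rules,
#' adjusted scores, final labels) and a flat CSV summary alongside.
#'
#' @param decisions named list (by image id) of [classifyImage()] results
#' @param jsonlPath output JSON-lines path
#' @param csvPath output CSV path (default: same stem, `.csv`)
#' @return invisibly, the two paths
#' @export
writeRuleDecisions <- function(decisions, jsonlPath,
                               csvPath = sub("\\.jsonl?$", ".csv", jsonlPath)) {
  con <- file(jsonlPath, "w")
  rows <- list()
  for (id in names(decisions)) {
    res <- decisions[[id]]
    rec <- list(image_id = id,
                adjusted_scores = as.list(scoreVector(res$adjustedScores)))
    for (tube in names(res$decisions)) {
      d <- res$decisions[[tube]]
      rec[[tube]] <- list(
        geometric_category = d@geometricCategory,
        fired_rules = as.list(d@firedRules),
        d_vertical_mm = d@dVerticalMm, d_euclidean_mm = d@dEuclideanMm,
        final_label = d@finalLabel
      )
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, tube = tube, geometric_category = d@geometricCategory,
        fired_rules = paste(d@firedRules, collapse = ";"),
        d_vertical_mm = d@dVerticalMm, d_euclidean_mm = d@dEuclideanMm,
        final_label = d@finalLabel, stringsAsFactors = FALSE
      )
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  close(con)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), tube = character(0))
  utils::write.csv(df, csvPath, row.names = FALSE)
  invisible(c(jsonlPath, csvPath))
}

.reportToList <- function(report) {
  pl <- report$perLabel
  pg <- report$perGroup
  sent <- function(v, status) ifelse(status == "ok", v, NA_real_)
  list(
    n_images = report$nImages, n_boot = report$nBoot, seed = report$seed,
    per_label = lapply(seq_len(nrow(pl)), function(i) list(
      label = pl$label[i], n = pl$n[i], n_pos = pl$nPos[i],
      auc = if (pl$status[i] == "ok") pl$auc[i] else "undefined",
      lo = if (pl$status[i] == "ok") pl$lo[i] else "undefined",
      hi = if (pl$status[i] == "ok") pl$hi[i] else "undefined"
    )),
    per_group = lapply(seq_len(nrow(pg)), function(i) list(
      group = pg$group[i], n_labels = pg$nLabels[i],
      auc = if (pg$status[i] == "ok") pg$auc[i] else "undefined",
      lo = if (pg$status[i] == "ok") pg$lo[i] else "undefined",
      hi = if (pg$status[i] == "ok") pg$hi[i] else "undefined"
    ))
  )
}

#' Write an evaluation report
#'
#' Emits `report.json` (undefined AUC cells serialized as the explicit
#' `"undefined"` sentinel, never silent NaN), CSV tables of the per-label and
#' group-averaged AUCs, and `manifest.json` recording seed, bootstrap count
#' and package version so a run is reproducible from the manifest alone. All
#' outputs are byte-deterministic given the same inputs and seed.
#'
#' @param report an `EvalReport` from [evaluateCohort()]
#' @param dir output directory (created if needed)
#' @param config optional list recorded verbatim in the manifest
#' @return invisibly, the written file paths
#' @export
writeEvalReport <- function(report, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(.reportToList(report), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  lp <- file.path(dir, "auc_per_label.csv")
  utils::write.csv(report$perLabel, lp, row.names = FALSE)
  gp <- file.path(dir, "auc_per_group.csv")
  utils::write.csv(report$perGroup, gp, row.names = FALSE)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = report$seed, n_boot = report$nBoot, n_images = report$nImages,
         package_version = as.character(utils::packageVersion("TubeLineQC")),
         config = config),
    mp, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(jp, lp, gp, mp))
}

#' Read back a JSON evaluation report
#'
#' Inverse of the JSON part of [writeEvalReport()]; `"undefined"` sentinels
#' become `NA` with status `"undefined"`.
#'
#' @param path path to `report.json`
#' @return an `EvalReport`-shaped list
#' @export
readEvalReport <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  num <- function(v) if (identical(v, "undefined")) NA_real_ else as.numeric(v)
  pl <- do.call(rbind, lapply(x$per_label, function(r) data.frame(
    label = r$label, n = as.integer(r$n), nPos = as.integer(r$n_pos),
    auc = num(r$auc), lo = num(r$lo), hi = num(r$hi),
    status = if (identical(r$auc, "undefined")) "undefined" else "ok",
    stringsAsFactors = FALSE
  )))
  pg <- do.call(rbind, lapply(x$per_group, function(r) data.frame(
    group = r$group, nLabels = as.integer(r$n_labels),
    auc = num(r$auc), lo = num(r$lo), hi = num(r$hi),
    status = if (identical(r$auc, "undefined")) "undefined" else "ok",
    stringsAsFactors = FALSE
  )))
  structure(list(perLabel = pl, perGroup = pg, nBoot = x$n_boot,
                 seed = x$seed, nImages = x$n_images),
            class = "EvalReport")
}

#' Serialize a RuleConfig to a plain list (YAML/JSON-ready)
#' @param cfg a [RuleConfig-class]
#' @return named list
#' @export
ruleConfigToList <- function(cfg) {
  list(ett_min_mm = cfg@ettMinMm, ett_max_mm = cfg@ettMaxMm,
       ngt_min_mm = cfg@ngtMinMm, ra_upper_third_mm = cfg@raUpperThirdMm,
       distance_mode = cfg@distanceMode,
       enabled_rules = as.list(cfg@enabledRules),
       boundary_inclusive_normal = cfg@boundaryInclusiveNormal)
}

#' Build a RuleConfig from a plain list (e.g. parsed YAML)
#' @param x named list as produced by [ruleConfigToList()]; missing entries
#'   keep their defaults
#' @return a [RuleConfig-class]
#' @export
ruleConfigFromList <- function(x) {
  d <- RuleConfig()
  RuleConfig(
    ettMinMm = x$ett_min_mm %||% d@ettMinMm,
    ettMaxMm = x$ett_max_mm %||% d@ettMaxMm,
    ngtMinMm = x$ngt_min_mm %||% d@ngtMinMm,
    raUpperThirdMm = x$ra_upper_third_mm %||% d@raUpperThirdMm,
    distanceMode = x$distance_mode %||% d@distanceMode,
    enabledRules = unlist(x$enabled_rules %||% d@enabledRules),
    boundaryInclusiveNormal = x$boundary_inclusive_normal %||% d@boundaryInclusiveNormal
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; a `rules:` section is parsed into a
#'   [RuleConfig-class], everything else is returned verbatim
#' @return list with `rules` ([RuleConfig-class]) and the remaining entries
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  rules <- ruleConfigFromList(x$rules %||% list())
  x$rules <- rules
  x
}
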