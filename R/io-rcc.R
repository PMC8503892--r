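#' Read a NanoString RCC lane file
#'
#' Parses the sectioned RCC dialect (bracket-headed sections such as
#' \code{<Header>}, \code{<Sample_Attributes>}, \code{<Lane_Attributes>} and
#' \code{<Code_Summary>}; one lane per file). \code{Code_Summary} rows are
#' \code{CodeClass,Name,Accession,Count} and counts must be non-negative
#' integers; any other value is a format error naming the offending probe.
#'
#' @param path path to an RCC file.
#' @return a validated \linkS4class{RccLane}. Attribute rows of the
#'   non-count sections are preserved, in file order, as
#'   \code{rccAttributes()} entries named \code{<Section>.<Key>}.
#' @examples
#' lanes <- simulateNanostringRun(nanoDesign(groups = c(PFA = 2), seed = 1))
#' f <- tempfile(fileext = ".RCC")
#' writeRcc(lanes[[1]], f)
#' identical(codeSummary(readRcc(f)), codeSummary(lanes[[1]]))
#' @export
readRcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^<[^/][^>]*>$", lines)
  if (!length(starts)) stop("not an RCC file (no sections): ", path)
  sections <- list()
  order_ <- character()
  for (s in starts) {
    name <- sub("^<([^>]*)>$", "\\1", lines[s])
    end <- grep(paste0("^</", name, ">$"), lines)
    end <- end[end > s][1L]
    if (is.na(end)) stop("RCC section <", name, "> is not closed in ", path)
    sections[[name]] <- lines[seq(s + 1L, length.out = max(0L, end - s - 1L))]
    order_ <- c(order_, name)
  }
  if (!"Code_Summary" %in% names(sections)) {
    stop("RCC format error: missing Code_Summary section in ", path)
  }

  attrs <- character()
  for (sec in setdiff(order_, "Code_Summary")) {
    for (row in sections[[sec]]) {
      kv <- strsplit(row, ",", fixed = TRUE)[[1L]]
      key <- kv[1L]
      val <- if (length(kv) > 1L) paste(kv[-1L], collapse = ",") else ""
      attrs[[paste(sec, key, sep = ".")]] <- val
    }
  }

  body <- sections[["Code_Summary"]]
  if (!length(body)) stop("RCC format error: empty Code_Summary in ", path)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(toupper(header[1:4]),
                 c("CODECLASS", "NAME", "ACCESSION", "COUNT"))) {
    stop("RCC format error: Code_Summary header must be ",
         "CodeClass,Name,Accession,Count")
  }
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  bad <- which(lengths(rows) < 4L)
  if (length(bad)) {
    stop("RCC format error: short Code_Summary row ", bad[1L] + 1L)
  }
  cs <- data.frame(
    codeClass = vapply(rows, `[`, "", 1L),
    name = vapply(rows, `[`, "", 2L),
    accession = vapply(rows, `[`, "", 3L),
    count = NA_integer_,
    stringsAsFactors = FALSE
  )
  rawCount <- vapply(rows, `[`, "", 4L)
  num <- suppressWarnings(as.numeric(rawCount))
  nonint <- is.na(num) | num < 0 | num != round(num)
  if (any(nonint)) {
    i <- which(nonint)[1L]
    stop("RCC format error: count \"", rawCount[i],
         "\" for gene ", cs$name[i], " is not a non-negative integer")
  }
  cs$count <- as.integer(num)

  getAttr <- function(key, default) {
    if (key %in% names(attrs)) unname(attrs[[key]]) else default
  }
  cart <- getAttr("Lane_Attributes.CartridgeID", "")
  RccLane(
    laneId = paste0(if (nzchar(cart)) paste0(cart, "_") else "",
                    getAttr("Lane_Attributes.ID", basename(path))),
    sampleName = getAttr("Sample_Attributes.ID", basename(path)),
    codeSummary = cs,
    attributes = attrs
  )
}

#' Write an RCC lane file
#'
#' Emits the sectioned RCC layout; \code{readRcc(writeRcc(lane))} returns a
#' lane equal to the input.
#'
#' @param lane an \linkS4class{RccLane}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRcc <- function(lane, path) {
  stopifnot(is(lane, "RccLane"))
  validObject(lane)
  attrs <- rccAttributes(lane)
  secs <- sub("\\..*$", "", names(attrs))
  keys <- sub("^[^.]*\\.", "", names(attrs))
  out <- character()
  for (sec in unique(secs)) {
    if (!nzchar(sec)) next
    idx <- which(secs == sec)
    out <- c(out, paste0("<", sec, ">"),
             paste0(keys[idx], ",", unname(attrs[idx])),
             paste0("</", sec, ">"))
  }
  if (!length(out)) {
    # minimal attribute sections so the file re-reads to the same lane
    out <- c("<Sample_Attributes>", paste0("ID,", sampleName(lane)),
             "</Sample_Attributes>",
             "<Lane_Attributes>", paste0("ID,", laneId(lane)),
             "</Lane_Attributes>")
  }
  cs <- codeSummary(lane)
  out <- c(out, "<Code_Summary>", "CodeClass,Name,Accession,Count",
           paste(cs$codeClass, cs$name, cs$accession, cs$count, sep = ","),
           "</Code_Summary>")
  writeLines(out, path)
  invisible(path)
}
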