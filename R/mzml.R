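## mzML export/import of PRM runs. Spectra are centroided, 64-bit float,
## uncompressed. MS3 scans carry a two-element precursorList (precursor,
## then MS3 selection), which is how multistage selection paths are
## represented in mzML; run-level metadata travels as userParams in
## fileDescription/fileContent.

b64_doubles <- function(x) {
  if (!length(x)) return("")
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

unb64_doubles <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  raw <- jsonlite::base64_dec(gsub("\\s", "", s))
  readBin(raw, "double", n = length(raw) %/% 8L, size = 8L,
          endian = "little")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

precursor_xml <- function(mz) {
  sprintf(paste0(
    "<precursor><isolationWindow>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000827\" ",
    "name=\"isolation window target m/z\" value=\"%.6f\" ",
    "unitCvRef=\"MS\" unitAccession=\"MS:1000040\" unitName=\"m/z\"/>",
    "</isolationWindow><selectedIonList count=\"1\"><selectedIon>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000744\" ",
    "name=\"selected ion m/z\" value=\"%.6f\" unitCvRef=\"MS\" ",
    "unitAccession=\"MS:1000040\" unitName=\"m/z\"/>",
    "</selectedIon></selectedIonList><activation>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000133\" ",
    "name=\"collision-induced dissociation\" value=\"\"/>",
    "</activation></precursor>"), mz, mz)
}

#' Write a PRM run as mzML
#'
#' @param run A [prm_run()].
#' @param path Destination `.mzML` path.
#' @return `path`, invisibly.
#' @seealso [read_mzml()]
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "prm_run"))
  sc <- run$scans
  pk <- split(run$peaks, factor(run$peaks$scan, levels = sc$scan))

  meta <- run$metadata
  spikes_str <- if (!is.null(meta$spikes))
    paste(sprintf("%s=%.10g", names(meta$spikes), meta$spikes),
          collapse = ";") else ""
  user <- sprintf("<userParam name=\"%s\" value=\"%s\"/>",
                  c("run_id", "sample_id", "protein_ug", "spikes"),
                  xml_escape(c(meta$run_id %||% "", meta$sample_id %||% "",
                               format(meta$protein_ug %||% ""),
                               spikes_str)))

  header <- c(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">",
    "<cvList count=\"2\">",
    paste0("<cv id=\"MS\" fullName=\"Proteomics Standards Initiative ",
           "Mass Spectrometry Ontology\" ",
           "URI=\"https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/",
           "master/psi-ms.obo\"/>"),
    paste0("<cv id=\"UO\" fullName=\"Unit Ontology\" ",
           "URI=\"https://raw.githubusercontent.com/bio-ontology-research",
           "-group/unit-ontology/master/unit.obo\"/>"),
    "</cvList>",
    "<fileDescription><fileContent>",
    paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000580\" ",
           "name=\"MSn spectrum\" value=\"\"/>"),
    paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000127\" ",
           "name=\"centroid spectrum\" value=\"\"/>"),
    user,
    "</fileContent></fileDescription>",
    paste0("<softwareList count=\"1\">",
           "<software id=\"prmlamin\" version=\"0.1.0\">",
           "<cvParam cvRef=\"MS\" accession=\"MS:1000799\" ",
           "name=\"custom unreleased software tool\" value=\"prmlamin\"/>",
           "</software></softwareList>"),
    paste0("<instrumentConfigurationList count=\"1\">",
           "<instrumentConfiguration id=\"IC1\">",
           "<cvParam cvRef=\"MS\" accession=\"MS:1000031\" ",
           "name=\"instrument model\" value=\"\"/>",
           "</instrumentConfiguration></instrumentConfigurationList>"),
    paste0("<dataProcessingList count=\"1\"><dataProcessing id=\"dp1\">",
           "<processingMethod order=\"1\" softwareRef=\"prmlamin\">",
           "<cvParam cvRef=\"MS\" accession=\"MS:1000544\" ",
           "name=\"Conversion to mzML\" value=\"\"/>",
           "</processingMethod></dataProcessing></dataProcessingList>"),
    sprintf("<run id=\"%s\" defaultInstrumentConfigurationRef=\"IC1\">",
            xml_escape(meta$run_id %||% "run")),
    sprintf("<spectrumList count=\"%d\" defaultDataProcessingRef=\"dp1\">",
            nrow(sc)))

  spectra <- vapply(seq_len(nrow(sc)), function(i) {
    p <- pk[[i]]
    mzb <- b64_doubles(p$mz)
    inb <- b64_doubles(p$intensity)
    prec <- precursor_xml(sc$sel1[i])
    nprec <- 1L
    if (sc$ms_level[i] >= 3L && is.finite(sc$sel2[i])) {
      prec <- paste0(prec, precursor_xml(sc$sel2[i]))
      nprec <- 2L
    }
    paste0(
      sprintf("<spectrum index=\"%d\" id=\"scan=%d\" defaultArrayLength=\"%d\">",
              i - 1L, sc$scan[i], nrow(p)),
      paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000580\" ",
             "name=\"MSn spectrum\" value=\"\"/>"),
      sprintf(paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000511\" ",
                     "name=\"ms level\" value=\"%d\"/>"), sc$ms_level[i]),
      paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000127\" ",
             "name=\"centroid spectrum\" value=\"\"/>"),
      "<scanList count=\"1\">",
      paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000795\" ",
             "name=\"no combination\" value=\"\"/>"),
      sprintf(paste0("<scan><cvParam cvRef=\"MS\" accession=\"MS:1000016\" ",
                     "name=\"scan start time\" value=\"%.8f\" ",
                     "unitCvRef=\"UO\" unitAccession=\"UO:0000031\" ",
                     "unitName=\"minute\"/></scan>"), sc$rt[i]),
      "</scanList>",
      sprintf("<precursorList count=\"%d\">%s</precursorList>", nprec, prec),
      "<binaryDataArrayList count=\"2\">",
      sprintf("<binaryDataArray encodedLength=\"%d\">", nchar(mzb)),
      paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000523\" ",
             "name=\"64-bit float\" value=\"\"/>",
             "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" ",
             "name=\"no compression\" value=\"\"/>",
             "<cvParam cvRef=\"MS\" accession=\"MS:1000514\" ",
             "name=\"m/z array\" value=\"\" unitCvRef=\"MS\" ",
             "unitAccession=\"MS:1000040\" unitName=\"m/z\"/>"),
      sprintf("<binary>%s</binary></binaryDataArray>", mzb),
      sprintf("<binaryDataArray encodedLength=\"%d\">", nchar(inb)),
      paste0("<cvParam cvRef=\"MS\" accession=\"MS:1000523\" ",
             "name=\"64-bit float\" value=\"\"/>",
             "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" ",
             "name=\"no compression\" value=\"\"/>",
             "<cvParam cvRef=\"MS\" accession=\"MS:1000515\" ",
             "name=\"intensity array\" value=\"\" unitCvRef=\"MS\" ",
             "unitAccession=\"MS:1000131\" unitName=\"number of detector ",
             "counts\"/>"),
      sprintf("<binary>%s</binary></binaryDataArray>", inb),
      "</binaryDataArrayList></spectrum>")
  }, character(1))

  footer <- c("</spectrumList></run></mzML>")
  writeLines(c(header, spectra, footer), path, useBytes = TRUE)
  invisible(path)
}

#' Read an mzML file as a PRM run
#'
#' Parses centroided targeted scans, including two-level precursor lists
#' (MS3 selection paths), scan start times and run-level userParam
#' metadata written by [write_mzml()]. Files from other writers are read
#' on a best-effort basis: `sel1`/`sel2` come from the precursor list in
#' document order.
#'
#' @param path `.mzML` path.
#' @return A [prm_run()].
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  px <- if ("d1" %in% names(ns)) "d1:" else ""
  q <- function(xpath, node = doc)
    xml2::xml_find_all(node, gsub("~", px, xpath), ns)
  q1 <- function(xpath, node = doc)
    xml2::xml_find_first(node, gsub("~", px, xpath), ns)

  meta <- list(run_id = NULL, sample_id = NULL, protein_ug = NULL,
               spikes = NULL)
  for (up in q("//~fileContent/~userParam")) {
    nm <- xml2::xml_attr(up, "name")
    val <- xml2::xml_attr(up, "value")
    if (nm == "protein_ug") {
      meta$protein_ug <- suppressWarnings(as.numeric(val))
    } else if (nm == "spikes") {
      if (nzchar(val)) {
        kv <- strsplit(strsplit(val, ";")[[1]], "=")
        meta$spikes <- stats::setNames(
          as.numeric(vapply(kv, `[`, character(1), 2L)),
          vapply(kv, `[`, character(1), 1L))
      }
    } else if (nm %in% c("run_id", "sample_id")) {
      meta[[nm]] <- val
    }
  }
  if (is.null(meta$run_id))
    meta$run_id <- xml2::xml_attr(q1("//~run"), "id")

  sp <- "//~spectrumList/~spectrum"
  n <- length(q(sp))
  if (!n) stop("no spectra found in ", path)

  # vectorised document-level queries (one result per spectrum, in order)
  lev <- as.integer(xml2::xml_attr(
    q(paste0(sp, "/~cvParam[@accession='MS:1000511']")), "value"))
  rtn <- q(paste0(sp,
    "/~scanList/~scan/~cvParam[@accession='MS:1000016']"))
  rt <- as.numeric(xml2::xml_attr(rtn, "value"))
  secs <- xml2::xml_attr(rtn, "unitName") == "second"
  rt[which(secs)] <- rt[which(secs)] / 60
  if (length(lev) != n || length(rt) != n)
    stop("unsupported mzML structure: expected one ms level and one scan ",
         "start time per spectrum")

  npre <- as.integer(xml2::xml_attr(
    q(paste0(sp, "/~precursorList")), "count"))
  sel_all <- as.numeric(xml2::xml_attr(
    q(paste0(sp, "/~precursorList/~precursor/~selectedIonList/~selectedIon",
             "/~cvParam[@accession='MS:1000744']")), "value"))
  if (length(npre) != n || sum(npre) != length(sel_all))
    stop("unsupported mzML structure: expected a precursorList with one ",
         "selected ion per precursor in every spectrum")
  idx <- rep(seq_len(n), npre)
  ord_in_spec <- sequence(npre)
  sel1 <- rep(NA_real_, n)
  sel2 <- rep(NA_real_, n)
  sel1[idx[ord_in_spec == 1L]] <- sel_all[ord_in_spec == 1L]
  sel2[idx[ord_in_spec == 2L]] <- sel_all[ord_in_spec == 2L]

  bda <- paste0(sp, "/~binaryDataArrayList/~binaryDataArray")
  mz_txt <- xml2::xml_text(
    q(paste0(bda, "[~cvParam[@accession='MS:1000514']]/~binary")))
  int_txt <- xml2::xml_text(
    q(paste0(bda, "[~cvParam[@accession='MS:1000515']]/~binary")))
  if (length(mz_txt) != n || length(int_txt) != n)
    stop("unsupported mzML structure: expected one m/z and one intensity ",
         "array per spectrum")
  mz_list <- lapply(mz_txt, unb64_doubles)
  int_list <- lapply(int_txt, unb64_doubles)
  npk <- lengths(mz_list)
  if (!identical(npk, lengths(int_list)))
    stop("m/z and intensity array lengths disagree")

  scans <- data.frame(scan = seq_len(n), rt = rt, ms_level = lev,
                      sel1 = sel1, sel2 = sel2)
  peaks <- data.frame(scan = rep(seq_len(n), npk),
                      mz = unlist(mz_list, use.names = FALSE),
                      intensity = unlist(int_list, use.names = FALSE))
  ord <- order(scans$rt, scans$scan)
  remap <- integer(n)
  remap[scans$scan[ord]] <- seq_len(n)
  peaks$scan <- remap[peaks$scan]
  scans <- scans[ord, ]
  scans$scan <- seq_len(n)
  rownames(scans) <- NULL
  peaks <- peaks[order(peaks$scan, peaks$mz), ]
  rownames(peaks) <- NULL
  prm_run(scans, peaks, metadata = meta)
}
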