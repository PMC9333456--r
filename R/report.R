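## Reporting and orchestration: run-configuration handling, GFF3/JSON
## annotation export, cross-paralog comparison reports and the scaled
## domain schematic. A thin command-line wrapper over these functions lives
## in inst/scripts/c2cartographer.R.

#' Run configuration with validated thresholds
#'
#' Collects the tunable thresholds of the pipeline with their defaults and
#' validates the documented ranges. The configuration is echoed as YAML next
#' to every output set so a run can be reproduced exactly.
#'
#' @param hbondCutoff Kabsch-Sander assignment threshold, kcal/mol (< 0).
#' @param minStrandLen minimum strand length, residues.
#' @param sandwichDist sheet-packing threshold, Angstrom.
#' @param subdomainMin insertion length that a subdomain must exceed.
#' @param conservationMin paralogs required for a conserved call.
#' @param pocketThreshold acidic slots required for binding-likely.
#' @param seed integer seed for seeded components.
#' @param logLevel "INFO" or "DEBUG".
#' @return named list of class \code{c2Config}.
#' @export
cartographyConfig <- function(hbondCutoff = -0.5, minStrandLen = 3L,
                              sandwichDist = 11, subdomainMin = 20L,
                              conservationMin = 2L, pocketThreshold = 4L,
                              seed = 1L, logLevel = "INFO") {
  if (hbondCutoff >= 0) .c2Stop("c2ConfigError", "hbondCutoff must be negative")
  if (minStrandLen < 2L) .c2Stop("c2ConfigError", "minStrandLen must be >= 2")
  if (sandwichDist <= 0 || sandwichDist > 30)
    .c2Stop("c2ConfigError", "sandwichDist must be in (0, 30] Angstrom")
  if (subdomainMin < 0L) .c2Stop("c2ConfigError", "subdomainMin must be >= 0")
  if (conservationMin < 1L) .c2Stop("c2ConfigError", "conservationMin must be >= 1")
  structure(list(hbondCutoff = hbondCutoff, minStrandLen = as.integer(minStrandLen),
                 sandwichDist = sandwichDist, subdomainMin = as.integer(subdomainMin),
                 conservationMin = as.integer(conservationMin),
                 pocketThreshold = as.integer(pocketThreshold),
                 seed = as.integer(seed), logLevel = logLevel),
            class = "c2Config")
}

#' Write / read a configuration echo
#' @param config a c2Config list.
#' @param path YAML file path.
#' @return the path (write) or the config (read).
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  do.call(cartographyConfig, yaml::read_yaml(path))
}

#' Convert C2 annotations to GRanges
#'
#' One range per feature in protein coordinates (1-based inclusive, seqname
#' = chain id): the domain span, its eight strands, the named loops and any
#' called subdomains.
#'
#' @param anns list of C2Annotation objects.
#' @return a \code{GRanges} with \code{type} and \code{Name} metadata.
#' @export
annotationsToGRanges <- function(anns) {
  rows <- list()
  for (k in seq_along(anns)) {
    ann <- anns[[k]]
    dn <- sprintf("C2_domain_%d", k)
    rows[[length(rows) + 1L]] <- data.frame(chain = ann@chain,
      start = ann@boundaries[1L], end = ann@boundaries[2L],
      type = "polypeptide_domain",
      name = sprintf("%s (%s)", dn, ann@topology))
    st <- ann@strands
    for (r in seq_len(nrow(st)))
      rows[[length(rows) + 1L]] <- data.frame(chain = ann@chain,
        start = st$first[r], end = st$last[r], type = "beta_strand",
        name = sprintf("%s_strand%d", dn, st$index[r]))
    for (nm in names(ann@loops)) {
      iv <- ann@loops[[nm]]
      if (.intervalLength(iv) == 0L) next
      apx <- match(nm, ann@apexLoops)
      rows[[length(rows) + 1L]] <- data.frame(chain = ann@chain,
        start = iv[1L], end = iv[2L], type = "loop",
        name = if (!is.na(apx)) sprintf("%s_%s_loop%d", dn, nm, apx)
               else sprintf("%s_%s", dn, nm))
    }
    sd <- ann@subdomains
    for (r in seq_len(nrow(sd)))
      rows[[length(rows) + 1L]] <- data.frame(chain = ann@chain,
        start = sd$first[r], end = sd$last[r], type = "subdomain",
        name = sprintf("%s_subdomain_%s", dn, sd$host_loop[r]))
  }
  if (length(rows) == 0L)
    return(GenomicRanges::GRanges())
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(seqnames = df$chain,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$Name <- df$name
  gr
}

## JSON-ready mirror of an annotation list.
.annotationsToList <- function(anns) {
  lapply(anns, function(ann) list(
    chain = ann@chain,
    topology = ann@topology,
    boundaries = as.integer(ann@boundaries),
    strands = ann@strands,
    loops = lapply(ann@loops, as.integer),
    apex_loops = ann@apexLoops,
    subdomains = ann@subdomains,
    pocket = ann@pocket))
}

#' Annotate structure files and write GFF3 + JSON reports
#'
#' Reads each input model, runs the full C2 recognition pipeline and writes
#' \code{<prefix>.gff3}, \code{<prefix>.json} and \code{<prefix>.config.yaml}
#' into \code{outDir}. Stage failures are reported with the input id and
#' stage name.
#'
#' @param paths character vector of PDB file paths (or a list of
#'   ProteinStructure objects).
#' @param outDir output directory (created if missing).
#' @param config a \code{\link{cartographyConfig}}.
#' @return invisibly, a named list of annotation lists per input.
#' @export
annotateStructure <- function(paths, outDir = ".", config = cartographyConfig()) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  out <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    s <- if (is(p, "ProteinStructure")) p else
      withCallingHandlers(readStructure(p),
        error = function(e) .c2Stop("c2StageError",
          sprintf("[read] %s: %s", p, conditionMessage(e))))
    anns <- tryCatch(
      annotateC2(s, sandwichDist = config$sandwichDist,
                 cutoff = config$hbondCutoff),
      error = function(e) .c2Stop("c2StageError",
        sprintf("[annotate] %s: %s", s@id, conditionMessage(e))))
    prefix <- file.path(outDir, s@id)
    rtracklayer::export(annotationsToGRanges(anns), paste0(prefix, ".gff3"),
                        format = "gff3")
    jsonlite::write_json(.annotationsToList(anns), paste0(prefix, ".json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeConfig(config, paste0(prefix, ".config.yaml"))
    out[[s@id]] <- anns
  }
  invisible(out)
}

#' Compare annotated C2 domains across paralogs
#'
#' Detects loop insertions of every paralog relative to the reference,
#' calls conserved subdomains and computes the overlay RMSD matrix. With
#' \code{outPrefix} set, writes \code{<prefix>.subdomains.tsv},
#' \code{<prefix>.rmsd.tsv} and \code{<prefix>.json}.
#'
#' @param domains named list (>= 2) of lists with \code{structure} and
#'   \code{annotation}.
#' @param reference reference domain (default: the packaged synthetic
#'   canonical Type-II model).
#' @param config a \code{\link{cartographyConfig}}.
#' @param outPrefix optional output path prefix.
#' @return list with \code{insertions}, \code{subdomains}, \code{overlay}.
#' @export
compareC2Domains <- function(domains, reference = NULL,
                             config = cartographyConfig(), outPrefix = NULL) {
  if (length(domains) < 2L)
    .c2Stop("c2UsageError", "at least two annotated domains required")
  if (is.null(reference)) reference <- referenceC2()
  refIn <- list(structure = reference$structure,
                annotation = reference$annotation)
  ins <- list(); sss <- list()
  for (nm in names(domains)) {
    ins[[nm]] <- detectInsertions(domains[[nm]], refIn)
    sss[[nm]] <- secondaryStructureString(domains[[nm]]$structure,
                                          domains[[nm]]$annotation@chain)
  }
  subs <- callSubdomains(ins, sss, minLength = config$subdomainMin,
                         conservationMin = config$conservationMin)
  ov <- overlayRmsd(domains)
  if (!is.null(outPrefix)) {
    utils::write.table(subs, paste0(outPrefix, ".subdomains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(domain = rownames(ov$matrix),
                                  round(ov$matrix, 4)),
                       paste0(outPrefix, ".rmsd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(subdomains = subs,
                              rmsd_mean = ov$mean,
                              rmsd = as.data.frame(ov$matrix)),
                         paste0(outPrefix, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  list(insertions = ins, subdomains = subs, overlay = ov)
}

#' Scaled domain schematic (SVG + TSV)
#'
#' One row per protein with domain boxes whose widths are proportional to
#' their residue spans (as in scaled domain diagrams of multi-domain
#' proteins). Overlapping spans are clipped with a warning. The TSV twin
#' lists the spans and lengths.
#'
#' @param domainTable data.frame with columns \code{protein}, \code{domain},
#'   \code{first}, \code{last} (1-based inclusive).
#' @param svgPath output SVG path.
#' @param tsvPath optional output TSV path.
#' @param scale residues per pixel-unit (box width = span / scale).
#' @return invisibly, the svg path.
#' @export
renderSchematic <- function(domainTable, svgPath, tsvPath = NULL, scale = 2) {
  need <- c("protein", "domain", "first", "last")
  if (!all(need %in% names(domainTable)))
    .c2Stop("c2UsageError", paste("domainTable needs columns:",
                                  paste(need, collapse = ", ")))
  prots <- unique(domainTable$protein)
  rowH <- 34; boxH <- 22; pad <- 90; top <- 24
  width <- pad + (if (nrow(domainTable)) max(domainTable$last) / scale else 0) + 20
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    width, top + rowH * length(prots)))
  palette <- c("#4878a8", "#b84848", "#50a050", "#b89048", "#8858a8",
               "#48a8a0", "#a05880", "#708090")
  for (k in seq_along(prots)) {
    sub <- domainTable[domainTable$protein == prots[k], , drop = FALSE]
    sub <- sub[order(sub$first), , drop = FALSE]
    y <- top + (k - 1L) * rowH
    lines <- c(lines, sprintf(
      '<text x="4" y="%.0f" font-size="12" font-family="sans-serif">%s</text>',
      y + boxH - 6, prots[k]))
    lastEnd <- -Inf
    for (r in seq_len(nrow(sub))) {
      f <- sub$first[r]; l <- sub$last[r]
      if (f <= lastEnd) {
        warning(sprintf("%s: domain %s overlaps the previous span; clipped",
                        prots[k], sub$domain[r]))
        f <- lastEnd + 1L
        if (f > l) next
      }
      lastEnd <- l
      x <- pad + (f - 1) / scale
      w <- (l - f + 1) / scale
      col <- palette[(r - 1L) %% length(palette) + 1L]
      lines <- c(lines, sprintf(
        '<rect x="%.2f" y="%.0f" width="%.2f" height="%.0f" fill="%s" stroke="#303030"/>',
        x, y, w, boxH, col), sprintf(
        '<text x="%.2f" y="%.0f" font-size="9" font-family="sans-serif" fill="#ffffff">%s</text>',
        x + 3, y + boxH - 8, sub$domain[r]))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, svgPath)
  if (!is.null(tsvPath)) {
    tab <- domainTable
    tab$length <- tab$last - tab$first + 1L
    utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(svgPath)
}

#' Simulate a sandwich and write its fixtures
#'
#' Convenience wrapper around \code{\link{buildSandwich}} writing the model
#' as PDB, its sequence as FASTA and the ground truth as JSON.
#'
#' @param spec a \linkS4class{SandwichSpec}.
#' @param outPrefix output path prefix.
#' @return invisibly, the built list.
#' @export
simulateSandwich <- function(spec = sandwichSpec(), outPrefix = "sandwich") {
  built <- buildSandwich(spec)
  writeStructure(built$structure, paste0(outPrefix, ".pdb"))
  writeFastaSequences(setNames(built$truth$sequence, built$structure@id),
                      paste0(outPrefix, ".fasta"))
  jsonlite::write_json(built$truth, paste0(outPrefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(built)
}
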