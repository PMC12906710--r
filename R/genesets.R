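#' @import methods
#' @importFrom stats median cor rnorm rbinom rnbinom rexp runif sd quantile
#'   wilcox.test p.adjust pchisq complete.cases lm coef setNames cov rlnorm
#' @importFrom utils read.csv write.csv packageVersion
NULL

setClassUnion("characterOrNULL", members = c("character", "NULL"))

#' GeneSet: a named, ordered collection of gene symbols
#'
#' A minimal container for a gene set: a unique short name, a category tag
#' used by the scoring stages to locate the putrescine-metabolism sets, and
#' an ordered vector of unique, uppercase gene symbols.
#'
#' @slot name Character scalar, non-empty; unique within a collection.
#' @slot category One of \code{put_biosynthesis}, \code{put_loss},
#'   \code{put_transport}, \code{t_function}, \code{pathway}, \code{other}.
#' @slot genes Character vector of unique gene symbols (uppercased at
#'   construction).
#'
#' @export
setClass("GeneSet",
  representation(name = "character", category = "character",
                 genes = "character"))

.geneset_categories <- c("put_biosynthesis", "put_loss", "put_transport",
                         "t_function", "pathway", "other")

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty character scalar")
  if (length(object@category) != 1L ||
      !object@category %in% .geneset_categories)
    msg <- c(msg, paste0("'category' must be one of: ",
                         paste(.geneset_categories, collapse = ", ")))
  if (length(object@genes) == 0L)
    msg <- c(msg, "'genes' must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' Gene symbols are uppercased once here so that downstream matching against
#' expression matrices (also uppercased at load) is case-insensitive in
#' effect; duplicates after uppercasing are removed keeping the first
#' occurrence.
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols.
#' @param category Category tag; see \linkS4class{GeneSet}.
#' @return A \linkS4class{GeneSet}.
#' @examples
#' GeneSet("cytotoxicity", c("GZMB", "PRF1"), "t_function")
#' @export
GeneSet <- function(name, genes, category = "other") {
  genes <- toupper(as.character(genes))
  genes <- genes[!duplicated(genes)]
  new("GeneSet", name = as.character(name), category = category,
      genes = genes)
}

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet \"", object@name, "\" (", object@category, "): ",
      length(object@genes), " genes\n", sep = "")
  cat("  ", paste(utils::head(object@genes, 8L), collapse = ", "),
      if (length(object@genes) > 8L) ", ..." else "", "\n", sep = "")
})

#' @describeIn GeneSet-accessors Set name.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @describeIn GeneSet-accessors Gene symbols of a set.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @describeIn GeneSet-accessors Category tag.
#' @export
setGeneric("setCategory", function(x) standardGeneric("setCategory"))

#' Accessors for GeneSet
#'
#' @param x A \linkS4class{GeneSet}.
#' @name GeneSet-accessors
NULL

#' @rdname GeneSet-accessors
#' @export
setMethod("setName", "GeneSet", function(x) x@name)
#' @rdname GeneSet-accessors
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)
#' @rdname GeneSet-accessors
#' @export
setMethod("setCategory", "GeneSet", function(x) x@category)

#' GeneSetCollection: a list of uniquely named gene sets
#'
#' @slot sets List of \linkS4class{GeneSet} objects with unique names.
#' @slot universe Optional character vector: the gene universe the sets were
#'   restricted to (\code{NULL} when unrestricted).
#'
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", universe = "characterOrNULL"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
    msg <- c(msg, "'sets' must be a list of GeneSet objects")
  nms <- vapply(object@sets, setName, character(1))
  if (anyDuplicated(nms))
    msg <- c(msg, "set names must be unique within a collection")
  if (!is.null(object@universe)) {
    members <- unique(unlist(lapply(object@sets, geneIds)))
    if (!all(members %in% object@universe))
      msg <- c(msg, "every member gene must belong to the recorded universe")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets List of \linkS4class{GeneSet} objects.
#' @param universe Optional gene universe (uppercased).
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets = list(), universe = NULL) {
  if (is(sets, "GeneSet")) sets <- list(sets)
  if (!is.null(universe)) universe <- toupper(as.character(universe))
  new("GeneSetCollection", sets = sets, universe = universe)
}

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets",
      if (!is.null(object@universe))
        paste0("(universe: ", length(object@universe), " genes)") else "",
      "\n")
  for (s in object@sets)
    cat("  ", setName(s), " [", setCategory(s), "]: ",
        length(geneIds(s)), " genes\n", sep = "")
})

#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("setNamesOf", function(x) standardGeneric("setNamesOf"))
#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' Accessors for GeneSetCollection
#'
#' \code{geneSets} returns the named list of member vectors, \code{setNamesOf}
#' the set names, \code{universe} the recorded universe (or \code{NULL}).
#'
#' @param x A \linkS4class{GeneSetCollection}.
#' @name GeneSetCollection-accessors
NULL

#' @rdname GeneSetCollection-accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) {
  out <- lapply(x@sets, geneIds)
  names(out) <- vapply(x@sets, setName, character(1))
  out
})
#' @rdname GeneSetCollection-accessors
#' @export
setMethod("setNamesOf", "GeneSetCollection",
          function(x) vapply(x@sets, setName, character(1)))
#' @rdname GeneSetCollection-accessors
#' @export
setMethod("universe", "GeneSetCollection", function(x) x@universe)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Subset a GeneSetCollection by set name or index
#'
#' @param x A \linkS4class{GeneSetCollection}.
#' @param i Set names or indices.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, setNamesOf(x))
  if (anyNA(i)) stop("unknown set name(s) in collection subset")
  GeneSetCollection(x@sets[i], universe = x@universe)
})

#' @rdname GeneSetCollection-accessors
#' @param name A single set name.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
  if (is.character(i)) i <- match(i, setNamesOf(x))
  if (is.na(i)) stop("unknown set name")
  x@sets[[i]]
})

#' Built-in putrescine-metabolism gene sets
#'
#' The three gene sets at the core of the scoring framework, grouped by their
#' contribution to cellular putrescine content: biosynthesis (ornithine
#' decarboxylase ODC1, agmatinase AGMAT, polyamine oxidase PAOX), loss
#' (spermidine synthase SRM, the antizymes OAZ1/OAZ2/OAZ3, and NQO1), and
#' transport (the solute carriers SLC22A1-3 and SLC7A1, the P-type ATPases
#' ATP13A2/ATP13A3, and glypican-1 GPC1). The antizyme shorthand OAZ1/2/3 is
#' expanded to three explicit symbols because scoring requires concrete
#' genes.
#'
#' @return A \linkS4class{GeneSetCollection} with exactly three sets named
#'   \code{put_biosynthesis}, \code{put_loss}, \code{put_transport}.
#' @examples
#' geneSets(builtinPutGenesets())
#' @export
builtinPutGenesets <- function() {
  GeneSetCollection(list(
    GeneSet("put_biosynthesis", c("ODC1", "AGMAT", "PAOX"),
            category = "put_biosynthesis"),
    GeneSet("put_loss", c("SRM", "OAZ1", "OAZ2", "OAZ3", "NQO1"),
            category = "put_loss"),
    GeneSet("put_transport",
            c("SLC22A1", "SLC22A2", "SLC22A3", "SLC7A1",
              "ATP13A2", "ATP13A3", "GPC1"),
            category = "put_transport")))
}

#' Placeholder T-cell functional gene sets
#'
#' Ten functional programmes used to summarise CXCR6+CD8+ T-cell state
#' (cytotoxicity, pro-inflammatory output, exhaustion, tissue residency, and
#' others). These memberships are field-standard placeholder lists assembled
#' for this package; studies with curated functional signatures should
#' substitute their own lists via \code{\link{parseGMT}} — every downstream
#' function accepts an arbitrary \linkS4class{GeneSetCollection} of category
#' \code{t_function}.
#'
#' @return A \linkS4class{GeneSetCollection} of 10 sets.
#' @export
builtinTFunctionalGenesets <- function() {
  defs <- list(
    cytotoxicity       = c("GZMB", "GZMA", "GZMH", "PRF1", "GNLY", "NKG7",
                           "KLRG1", "FASLG"),
    pro_inflammatory   = c("IFNG", "TNF", "IL2", "IL17A", "CSF2", "LTA",
                           "IL21", "TNFSF14"),
    exhaustion         = c("PDCD1", "HAVCR2", "LAG3", "CTLA4", "TIGIT",
                           "TOX", "ENTPD1", "BTLA"),
    tissue_residency   = c("ITGAE", "ITGA1", "ZNF683", "CD69", "RGS1",
                           "CXCL13", "DUSP6", "CRTAM"),
    naive_memory       = c("TCF7", "SELL", "CCR7", "LEF1", "IL7R", "BACH2",
                           "FOXP1", "KLF2"),
    costimulatory      = c("CD28", "ICOS", "TNFRSF9", "TNFRSF4", "CD27",
                           "TNFRSF18", "CD40LG", "SLAMF1"),
    cytokine_receptor  = c("IL2RA", "IL2RB", "IL12RB2", "IL18R1", "IL21R",
                           "IFNGR1", "IL10RA", "IL15RA"),
    stress_response    = c("HSPA1A", "HSPA1B", "DNAJB1", "HSPH1", "BAG3",
                           "HSPB1", "HSPD1", "UBC"),
    proliferation      = c("MKI67", "TOP2A", "CCNB1", "CDK1", "PCNA",
                           "TYMS", "BIRC5", "AURKB"),
    apoptosis          = c("BAX", "BCL2L11", "CASP3", "CASP8", "FAS",
                           "TP53", "BID", "APAF1"))
  GeneSetCollection(lapply(names(defs), function(nm)
    GeneSet(nm, defs[[nm]], category = "t_function")))
}

#' Parse a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then one gene symbol per
#' remaining field. The description field is discarded; duplicate symbols
#' within a line are removed keeping the first occurrence; symbols are
#' uppercased.
#'
#' @param path Path to a GMT file.
#' @param category Category assigned to every parsed set.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
parseGMT <- function(path, category = "other") {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    sets[[i]] <- GeneSet(fields[[1]], fields[-(1:2)], category = category)
  }
  nms <- vapply(sets, setName, character(1))
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT file: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  GeneSetCollection(sets)
}

#' Write a GeneSetCollection to GMT
#'
#' The description field is written as \code{"na"}; \code{parseGMT} discards
#' it, so write-then-parse is the identity on collections.
#'
#' @param coll A \linkS4class{GeneSetCollection}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(coll, path) {
  stopifnot(is(coll, "GeneSetCollection"))
  lines <- vapply(coll@sets, function(s)
    paste(c(setName(s), "na", geneIds(s)), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to a gene universe
#'
#' Each set is intersected with \code{genes} (order preserved); sets emptied
#' by the intersection are dropped with a warning. The universe is recorded
#' on the returned collection. Restricting twice with the same universe is a
#' no-op.
#'
#' @param coll A \linkS4class{GeneSetCollection}.
#' @param genes Character vector of gene symbols (the measured universe).
#' @return A restricted \linkS4class{GeneSetCollection}.
#' @export
restrictToUniverse <- function(coll, genes) {
  stopifnot(is(coll, "GeneSetCollection"), length(genes) > 0L)
  genes <- toupper(as.character(genes))
  kept <- list()
  for (s in coll@sets) {
    g <- geneIds(s)[geneIds(s) %in% genes]
    if (length(g) == 0L) {
      warning("gene set '", setName(s),
              "' has no members in the universe; dropped")
    } else {
      kept[[length(kept) + 1L]] <- GeneSet(setName(s), g,
                                           category = setCategory(s))
    }
  }
  if (length(kept) == 0L)
    stop("all gene sets were emptied by the universe restriction")
  GeneSetCollection(kept, universe = genes)
}
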