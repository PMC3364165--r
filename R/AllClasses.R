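#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats setNames runif
#' @importFrom utils head read.delim write.table
NULL

#' BarcodeLibrary: an anchored, quality-screened barcode reference library
#'
#' A \code{BarcodeLibrary} holds a set of COI barcode sequences anchored to
#' the standard 658-site barcode coordinate frame together with their
#' specimen metadata (taxonomy, identification confidence, locality) and a
#' per-sequence quality-control report (reading-frame stop codons, internal
#' indels, minimum-length screen).
#'
#' Sequences are stored as a \code{DNAStringSet}; a sequence of length L
#' anchored at \code{start} covers frame sites \code{start .. start + L - 1}.
#' Full-length barcodes are anchored at site 1; shorter records are treated
#' as 5'-anchored fragments unless an explicit start is supplied.
#'
#' @slot sequences \code{DNAStringSet} of barcode sequences, named by
#'   specimen id (IUPAC ambiguity codes and \code{N} allowed).
#' @slot startPos integer vector, 1-based anchor of each sequence on the
#'   barcode frame.
#' @slot frameLength integer(1), number of sites in the coordinate frame
#'   (658 for the Folmer COI barcode).
#' @slot specimens \code{DataFrame} of specimen metadata, one row per
#'   sequence (row names are specimen ids); columns include \code{family},
#'   \code{genus}, \code{species_label}, \code{is_provisional},
#'   \code{id_confidence}.
#' @slot qc \code{DataFrame} of per-sequence QC results with columns
#'   \code{frame_offset}, \code{stop_positions}, \code{has_indel},
#'   \code{length}, \code{qc_status}.
#'
#' @seealso \code{\link{readBarcodeFasta}}, \code{\link{qcSequence}},
#'   \code{\link{k2pDistanceMatrix}}
#' @exportClass BarcodeLibrary
setClass("BarcodeLibrary",
    slots = c(
        sequences   = "DNAStringSet",
        startPos    = "integer",
        frameLength = "integer",
        specimens   = "DFrame",
        qc          = "DFrame"
    )
)

setValidity("BarcodeLibrary", function(object) {
    msg <- character()
    ids <- names(object@sequences)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        msg <- c(msg, "all sequences must be named by specimen id")
    if (anyDuplicated(ids))
        msg <- c(msg, paste0("duplicate specimen ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    n <- length(object@sequences)
    if (length(object@startPos) != n)
        msg <- c(msg, "startPos must parallel sequences")
    if (length(object@frameLength) != 1L || object@frameLength < 1L)
        msg <- c(msg, "frameLength must be a single positive integer")
    w <- Biostrings::width(object@sequences)
    if (n > 0L && (any(object@startPos < 1L) ||
                   any(object@startPos + w - 1L > object@frameLength)))
        msg <- c(msg, "sequences must lie within the barcode frame")
    if (nrow(object@specimens) != n ||
        !identical(rownames(object@specimens), ids))
        msg <- c(msg, "specimens rows must match sequence names")
    if (nrow(object@qc) != n)
        msg <- c(msg, "qc rows must match sequences")
    lat <- object@specimens[["latitude"]]
    if (!is.null(lat) && any(!is.na(lat) & (lat < -90 | lat > 90)))
        msg <- c(msg, "latitude out of [-90, 90]")
    lon <- object@specimens[["longitude"]]
    if (!is.null(lon) && any(!is.na(lon) & (lon < -180 | lon > 180)))
        msg <- c(msg, "longitude out of [-180, 180]")
    if (length(msg)) msg else TRUE
})

#' K2PDistanceMatrix: pairwise K2P distances with pairwise deletion
#'
#' Symmetric matrix of Kimura 2-parameter distances among specimens,
#' together with the per-pair number of compared sites and the observed
#' transition (P) and transversion (Q) proportions. Entries are \code{NA}
#' ("undefined") when the site overlap is below the minimum or when the
#' distance is saturated (a logarithm argument is non-positive).
#'
#' @slot d numeric matrix of distances (substitutions/site); \code{NA}
#'   where undefined; zero diagonal.
#' @slot n integer matrix of compared (both-unambiguous) site counts.
#' @slot P,Q numeric matrices of transition / transversion proportions.
#' @slot minOverlap integer(1), the minimum overlap used.
#'
#' @seealso \code{\link{k2pDistance}}, \code{\link{k2pDistanceMatrix}}
#' @exportClass K2PDistanceMatrix
setClass("K2PDistanceMatrix",
    slots = c(d = "matrix", n = "matrix", P = "matrix", Q = "matrix",
              minOverlap = "integer")
)

setValidity("K2PDistanceMatrix", function(object) {
    msg <- character()
    d <- object@d
    ids <- rownames(d)
    if (is.null(ids) || !identical(ids, colnames(d)))
        msg <- c(msg, "d must have identical row/col specimen ids")
    if (!isTRUE(all.equal(d, t(d))) && !all(is.na(d) == t(is.na(d))))
        msg <- c(msg, "d must be symmetric")
    if (any(diag(d) != 0))
        msg <- c(msg, "diagonal must be exactly 0")
    if (any(d < 0, na.rm = TRUE))
        msg <- c(msg, "defined distances must be >= 0")
    for (s in c("n", "P", "Q"))
        if (!identical(dim(slot(object, s)), dim(d)))
            msg <- c(msg, sprintf("slot %s must match dim(d)", s))
    if (length(msg)) msg else TRUE
})

#' Audit configuration
#'
#' Thresholds and scopes for the library audit. All distance thresholds are
#' proportions (substitutions/site), not percent.
#'
#' @slot t_deep deep-divergence flag threshold on MXID (default 0.022,
#'   i.e. 2.2\%); strict \code{>}.
#' @slot t_split deep-cluster cutoff for single-linkage haplotype clusters
#'   (default 0.050).
#' @slot t_assign name-assignment threshold (default 0.020); a query is
#'   linked to a reference species when its distance is strictly below.
#' @slot mnid_scope scope of the minimum interspecific distance search:
#'   \code{"genus"} (congeners, default), \code{"family"}, or \code{"all"}.
#' @slot min_overlap minimum number of compared sites for a defined
#'   distance (default 100).
#' @slot min_len minimum retained sequence length (default 300 sites).
#' @seealso \code{\link{auditConfig}}
#' @exportClass AuditConfig
setClass("AuditConfig",
    slots = c(t_deep = "numeric", t_split = "numeric", t_assign = "numeric",
              mnid_scope = "character", min_overlap = "integer",
              min_len = "integer"),
    prototype = list(t_deep = 0.022, t_split = 0.050, t_assign = 0.020,
                     mnid_scope = "genus", min_overlap = 100L,
                     min_len = 300L)
)

setValidity("AuditConfig", function(object) {
    msg <- character()
    if (object@t_assign <= 0) msg <- c(msg, "t_assign must be > 0")
    if (!(object@t_deep < object@t_split && object@t_split < 1))
        msg <- c(msg, "need t_deep < t_split < 1")
    if (!object@mnid_scope %in% c("genus", "family", "all"))
        msg <- c(msg, "mnid_scope must be genus, family or all")
    if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic barcode libraries
#'
#' Parameters of the synthetic COI-library generator. Divergence depths are
#' expected pairwise K2P distances (substitutions/site); under the star
#' radiation used by the generator the expected pairwise distance between
#' two tips radiating from a common ancestor at depth t/2 is t.
#'
#' @slot seed integer RNG seed; a given seed yields byte-identical output.
#' @slot n_genera,species_per_genus,specimens_per_species library shape
#'   (defaults 4 genera x 5 species x 10 specimens).
#' @slot seq_length barcode length in sites (default 658).
#' @slot kappa transition/transversion rate ratio of the substitution
#'   process (default 3).
#' @slot intra_depth expected intraspecific (within-cluster) pairwise
#'   distance (default 0.02).
#' @slot inter_depth expected congeneric interspecific pairwise distance
#'   (default 0.12).
#' @slot between_genus_depth expected pairwise distance between specimens
#'   of different genera in the same family (default 0.30); keeps
#'   cross-genus K2P distances defined (unsaturated) so family-scope
#'   trees can be built.
#' @slot cryptic_fraction share of species built as cryptic complexes of
#'   2-3 clusters (default 0.20; count is floor(fraction * n_species)).
#' @slot split_depth divergence between cryptic clusters (default 0.08).
#' @slot fragment_fraction,fragment_length share of sequences truncated to
#'   a 5' fragment and the fragment length (defaults 0.10 and 325).
#' @slot ambiguity_rate per-site probability of masking to N (default 0).
#' @slot misid_count number of specimens whose metadata label is swapped to
#'   a random congeneric species (default 5).
#' @seealso \code{\link{simulationConfig}},
#'   \code{\link{simulateReferenceLibrary}}
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    slots = c(seed = "integer", n_genera = "integer",
              species_per_genus = "integer", specimens_per_species = "integer",
              seq_length = "integer", kappa = "numeric",
              intra_depth = "numeric", inter_depth = "numeric",
              between_genus_depth = "numeric",
              cryptic_fraction = "numeric", split_depth = "numeric",
              fragment_fraction = "numeric", fragment_length = "integer",
              ambiguity_rate = "numeric", misid_count = "integer"),
    prototype = list(seed = 1L, n_genera = 4L, species_per_genus = 5L,
                     specimens_per_species = 10L, seq_length = 658L,
                     kappa = 3, intra_depth = 0.02, inter_depth = 0.12,
                     between_genus_depth = 0.30,
                     cryptic_fraction = 0.20, split_depth = 0.08,
                     fragment_fraction = 0.10, fragment_length = 325L,
                     ambiguity_rate = 0, misid_count = 5L)
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@n_genera < 1L || object@species_per_genus < 1L ||
        object@specimens_per_species < 1L)
        msg <- c(msg, "library shape counts must be >= 1")
    rates <- c(object@kappa, object@intra_depth, object@inter_depth,
               object@between_genus_depth, object@split_depth,
               object@ambiguity_rate)
    if (any(rates < 0)) msg <- c(msg, "rates and depths must be >= 0")
    if (object@split_depth < object@intra_depth ||
        object@inter_depth < object@intra_depth ||
        object@between_genus_depth < object@inter_depth)
        msg <- c(msg, paste0("depths must nest: intra_depth <= split_depth",
                             " and intra_depth <= inter_depth <= ",
                             "between_genus_depth"))
    if (object@cryptic_fraction < 0 || object@cryptic_fraction > 1)
        msg <- c(msg, "cryptic_fraction must be in [0, 1]")
    if (object@fragment_fraction < 0 || object@fragment_fraction > 1)
        msg <- c(msg, "fragment_fraction must be in [0, 1]")
    if (object@seq_length < 3L) msg <- c(msg, "seq_length too short")
    if (object@fragment_length > object@seq_length)
        msg <- c(msg, "fragment_length exceeds seq_length")
    if (object@misid_count < 0L) msg <- c(msg, "misid_count must be >= 0")
    if (length(msg)) msg else TRUE
})
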