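# Shorthand lipid nomenclature: parsing, serialisation, class taxonomy and
# class totals.

# Closed vocabulary of base class codes accepted by the parser.  Ether
# subclasses are derived from the O-/P- prefix inside the parentheses, e.g.
# "PC(O-36:3)" has class code "PC(O)".
.base_classes <- c(
  "PC", "PE", "PS", "PI", "PG", "SM", "Cer", "dhCer", "HexCer", "Hex2Cer",
  "Hex3Cer", "GM3", "GM1", "TG", "DG", "CE", "DE", "LPC", "LPE", "AC"
)

# Classes carrying a single fatty-acid/acyl chain; one chain token fully
# specifies the species.  Everything else with a single x:y token is a sum
# composition.
.single_chain_classes <- c("CE", "DE", "LPC", "LPE", "AC")

# Expected number of chains when the species is fully specified.
.n_chains_full <- function(class_base) {
  if (class_base %in% .single_chain_classes) 1L
  else if (class_base %in% c("TG")) 3L
  else 2L
}

# Known branched-chain tags: tag -> c(carbons, double_bonds).  MHDA is
# methylhexadecanoic acid, counted as a 16:0 chain with a branch annotation.
.branch_tags <- list(MHDA = c(16L, 0L))

.malformed <- function(name, token, what) {
  stop(sprintf("malformed lipid name '%s': %s in token '%s'", name, what, token),
       call. = FALSE)
}

.parse_chain_token <- function(token, name, ether = "") {
  m <- regmatches(token, regexec("^(\\d+)-([A-Za-z]+)$", token))[[1]]
  if (length(m) == 3L) {
    tag <- m[3]
    if (!tag %in% names(.branch_tags))
      .malformed(name, token, "unknown branch tag")
    cd <- .branch_tags[[tag]]
    return(list(carbons = cd[1], double_bonds = cd[2], ether = "",
                sphingoid = FALSE, branch = token))
  }
  m <- regmatches(token, regexec("^(d?)(\\d+):(\\d+)$", token))[[1]]
  if (length(m) != 4L)
    .malformed(name, token, "non-numeric or unrecognised chain field")
  list(carbons = as.integer(m[3]), double_bonds = as.integer(m[4]),
       ether = ether, sphingoid = m[2] == "d", branch = NA_character_)
}

#' Parse a shorthand lipid species name
#'
#' Parses names written in the shorthand nomenclature used for targeted
#' plasma lipidomics panels, e.g. \code{"SM(d18:1/24:1)"},
#' \code{"PC(P-17:0/20:4) (a)"}, \code{"TG(O-52:2) [NL-16:0]"},
#' \code{"PC(15-MHDA_18:1)"} or \code{"LPC(20:2) [sn1]"}.
#'
#' The grammar is \code{CLASS(prefix-chain[/chain][_chain]) [tags]}:
#' an \code{O-} or \code{P-} prefix marks an alkyl or alkenyl (plasmalogen)
#' ether linkage and moves the species into the \code{CLASS(O)} /
#' \code{CLASS(P)} subclass; a leading \code{d} on a sphingolipid chain marks
#' the sphingoid base; \code{"/"} separates chains of known sn position,
#' \code{"_"} chains of unknown position; trailing \code{(a)}/\code{(b)}
#' label chromatographically separated but structurally unresolved isomers;
#' \code{[sn1]} records a resolved sn position, and \code{[NL-x:y]} a chain
#' identified from a neutral loss.  A single \code{x:y} token in a
#' multi-chain class (e.g. \code{"SM(43:1)"}) is a sum composition.
#'
#' @param name A single lipid species name.
#' @return An object of class \code{"lipid_species"}: a list with fields
#'   \code{raw_name}, \code{class_code}, \code{class_base},
#'   \code{total_carbons}, \code{total_double_bonds}, \code{chains} (list of
#'   chain descriptors with \code{carbons}, \code{double_bonds},
#'   \code{ether}, \code{sphingoid}, \code{branch}), \code{sn_known},
#'   \code{isomer_label} (\code{""}, \code{"a"} or \code{"b"}),
#'   \code{sn_tag}, \code{neutral_loss_tag}.
#' @examples
#' sp <- parse_lipid_name("SM(d18:1/24:1)")
#' sp$total_carbons        # 42
#' sp$total_double_bonds   # 2
#' format(parse_lipid_name("PC(P-17:0/20:4) (a)"))
#' @seealso [format.lipid_species()], [lipid_registry()]
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  raw <- name
  s <- trimws(name)
  if (!nzchar(s)) stop("lipid name is empty", call. = FALSE)
  if (lengths(regmatches(s, gregexpr("(", s, fixed = TRUE))) !=
      lengths(regmatches(s, gregexpr(")", s, fixed = TRUE))))
    .malformed(raw, s, "unbalanced parentheses")

  isomer <- ""
  sn_tag <- NA_character_
  nl_tag <- NULL
  # strip trailing tags in any order
  repeat {
    if (grepl("\\s*\\(([ab])\\)$", s)) {
      isomer <- sub("^.*\\(([ab])\\)$", "\\1", s)
      s <- trimws(sub("\\s*\\([ab]\\)$", "", s))
    } else if (grepl("\\s*\\[sn(\\d+)\\]$", s)) {
      sn_tag <- sub("^.*\\[(sn\\d+)\\]$", "\\1", s)
      s <- trimws(sub("\\s*\\[sn\\d+\\]$", "", s))
    } else if (grepl("\\s*\\[NL-[^]]+\\]$", s)) {
      tok <- sub("^.*\\[NL-([^]]+)\\]$", "\\1", s)
      nl_tag <- .parse_chain_token(tok, raw)
      s <- trimws(sub("\\s*\\[NL-[^]]+\\]$", "", s))
    } else break
  }

  m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)\\((.+)\\)$", s))[[1]]
  if (length(m) != 3L)
    .malformed(raw, s, "name does not match CLASS(chains)")
  class_base <- m[2]
  interior <- m[3]
  if (!class_base %in% .base_classes)
    .malformed(raw, class_base, "unknown class code")

  ether <- ""
  if (grepl("^[OP]-", interior)) {
    ether <- substr(interior, 1L, 1L)
    interior <- substring(interior, 3L)
  }
  class_code <- if (nzchar(ether)) sprintf("%s(%s)", class_base, ether)
                else class_base

  sn_known <- grepl("/", interior, fixed = TRUE)
  if (sn_known && grepl("_", interior, fixed = TRUE))
    .malformed(raw, interior, "mixed '/' and '_' chain separators")
  tokens <- strsplit(interior, "[/_]")[[1]]
  if (any(!nzchar(tokens)))
    .malformed(raw, interior, "empty chain token")

  chains <- vector("list", length(tokens))
  for (i in seq_along(tokens))
    chains[[i]] <- .parse_chain_token(tokens[i], raw,
                                      ether = if (i == 1L) ether else "")

  n_full <- .n_chains_full(class_base)
  sum_composition <- length(tokens) == 1L && n_full > 1L &&
    is.na(chains[[1L]]$branch) && !chains[[1L]]$sphingoid
  if (sum_composition) {
    total_c <- chains[[1L]]$carbons
    total_db <- chains[[1L]]$double_bonds
    chains <- list()
  } else {
    total_c <- sum(vapply(chains, `[[`, integer(1), "carbons"))
    total_db <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
  }

  structure(list(
    raw_name = raw,
    class_code = class_code,
    class_base = class_base,
    total_carbons = total_c,
    total_double_bonds = total_db,
    chains = chains,
    sum_composition = sum_composition,
    composition_token = if (sum_composition) tokens[1L] else NA_character_,
    sn_known = sn_known,
    isomer_label = isomer,
    sn_tag = sn_tag,
    neutral_loss_tag = nl_tag
  ), class = "lipid_species")
}

.format_chain <- function(ch) {
  if (!is.na(ch$branch)) return(ch$branch)
  sprintf("%s%d:%d", if (isTRUE(ch$sphingoid)) "d" else "",
          ch$carbons, ch$double_bonds)
}

#' Serialise a parsed lipid species back to its shorthand name
#'
#' Canonical serialisation; \code{format(parse_lipid_name(x)) == x} for
#' every name in the supported grammar.
#'
#' @param x A \code{"lipid_species"} object.
#' @param ... Unused.
#' @return The shorthand name as a character scalar.
#' @export
format.lipid_species <- function(x, ...) {
  ether_prefix <- ""
  if (grepl("\\((O|P)\\)$", x$class_code))
    ether_prefix <- paste0(sub("^.*\\((O|P)\\)$", "\\1", x$class_code), "-")
  interior <- if (x$sum_composition) x$composition_token
  else paste(vapply(x$chains, .format_chain, character(1)),
             collapse = if (x$sn_known) "/" else "_")
  out <- sprintf("%s(%s%s)", x$class_base, ether_prefix, interior)
  if (!is.na(x$sn_tag)) out <- sprintf("%s [%s]", out, x$sn_tag)
  if (!is.null(x$neutral_loss_tag))
    out <- sprintf("%s [NL-%s]", out, .format_chain(x$neutral_loss_tag))
  if (nzchar(x$isomer_label)) out <- sprintf("%s (%s)", out, x$isomer_label)
  out
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  class=%s  %d:%d  (%d chain%s%s)\n",
              format(x), x$class_code, x$total_carbons, x$total_double_bonds,
              length(x$chains), if (length(x$chains) == 1L) "" else "s",
              if (x$sum_composition) ", sum composition" else ""))
  invisible(x)
}

#' Build a lipid panel registry
#'
#' The registry maps every species name on the panel to exactly one lipid
#' class code; class codes are taken from the registry input (they need not
#' be re-derivable from the name, although [parse_lipid_name()] is applied
#' to validate every name).
#'
#' @param species Character vector of species names, or a data.frame with
#'   columns \code{species_name} and \code{class_code}.
#' @param class_code Character vector of class codes (recycled against
#'   \code{species} if that is a character vector).
#' @return An object of class \code{"panel_registry"}: list with
#'   \code{species} (data.frame \code{species_name}, \code{class_code}),
#'   \code{class_of} (named character), \code{n_classes}.
#' @examples
#' reg <- lipid_registry(c("SM(d18:1/24:1)", "SM(d18:2/24:0)", "CE(17:0)"),
#'                       c("SM", "SM", "CE"))
#' reg$n_classes
#' @export
lipid_registry <- function(species, class_code = NULL) {
  if (is.data.frame(species)) {
    df <- species
    if (!all(c("species_name", "class_code") %in% names(df)))
      stop("registry data.frame needs columns 'species_name' and 'class_code'")
    df <- df[, c("species_name", "class_code")]
  } else {
    df <- data.frame(species_name = as.character(species),
                     class_code = as.character(class_code),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$species_name))
    stop("duplicated species names in registry: ",
         paste(unique(df$species_name[duplicated(df$species_name)]),
               collapse = ", "))
  for (nm in df$species_name) parse_lipid_name(nm)  # validate grammar
  class_of <- stats::setNames(df$class_code, df$species_name)
  structure(list(species = df, class_of = class_of,
                 n_classes = length(unique(df$class_code))),
            class = "panel_registry")
}

#' @export
print.panel_registry <- function(x, ...) {
  cat(sprintf("<panel_registry> %d species in %d classes\n",
              nrow(x$species), x$n_classes))
  invisible(x)
}

#' Read a panel registry from a delimited text file
#'
#' Expects a header line and two columns, \code{species_name} and
#' \code{class_code} (tab- or comma-separated, UTF-8).
#'
#' @param path File path.
#' @param sep Field separator; default tab.
#' @return A \code{"panel_registry"}.
#' @export
read_registry <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  lipid_registry(df)
}

#' Sum species concentrations into lipid class totals
#'
#' Class totals are the arithmetic sums of the member species on the raw
#' concentration scale (sums are only meaningful before any log
#' transformation).
#'
#' @param concentrations Numeric matrix or data.frame, samples in rows,
#'   species in columns (column names must appear in the registry).
#' @param registry A \code{"panel_registry"}.
#' @return Numeric matrix, samples x classes, one column per distinct class
#'   present among the input columns.
#' @examples
#' reg <- lipid_registry(c("CE(17:0)", "CE(18:1)", "AC(13:0)"),
#'                       c("CE", "CE", "AC"))
#' m <- rbind(c(1.5, 2.5, 3), c(2, 3, 4))
#' colnames(m) <- reg$species$species_name
#' class_totals(m, reg)
#' @export
class_totals <- function(concentrations, registry) {
  stopifnot(inherits(registry, "panel_registry"))
  m <- as.matrix(concentrations)
  if (is.null(colnames(m))) stop("concentration table must have column names")
  unknown <- setdiff(colnames(m), names(registry$class_of))
  if (length(unknown))
    stop("species not in registry: ", paste(unknown, collapse = ", "))
  cls <- registry$class_of[colnames(m)]
  classes <- unique(cls)
  out <- vapply(classes,
                function(cl) rowSums(m[, cls == cl, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(rownames(m), classes))
  colnames(out) <- classes
  rownames(out) <- rownames(m)
  out
}
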