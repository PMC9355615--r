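## Partition an OTU table into total / mycorrhizal / saprotrophic /
## pathotrophic sub-tables under FUNGuild-style inclusion rules: only
## Highly Probable or Probable annotations with a single trophic mode are
## included, endophytes are dropped, and mycorrhizal = arbuscular + ecto.

#' Classify one annotation record into an analysis guild
#'
#' Rules, applied in order: excluded if confidence is `Possible` or
#' `Unassigned`, if the trophic mode names more than one mode (contains the
#' `-` separator), or if the guild string mentions endophytes; else
#' mycorrhizal if the guild contains "Arbuscular Mycorrhizal" or
#' "Ectomycorrhizal" (case-insensitive substring); else saprotrophic if the
#' trophic mode is `Saprotroph`; pathotrophic if `Pathotroph`; anything else
#' is excluded.
#'
#' @param trophic_mode,guild,confidence annotation fields (vectorized).
#' @return character vector over `{mycorrhizal, saprotrophic, pathotrophic,
#'   excluded}`.
#' @export
classify_otu <- function(trophic_mode, guild, confidence) {
  n <- length(trophic_mode)
  stopifnot(length(guild) == n, length(confidence) == n)
  out <- rep("excluded", n)
  ok_conf <- confidence %in% c("Highly Probable", "Probable")
  single <- !grepl("-", trophic_mode, fixed = TRUE)
  not_endo <- !grepl("endophyte", guild, ignore.case = TRUE)
  ok <- ok_conf & single & not_endo
  myc <- ok & (grepl("arbuscular mycorrhizal", guild, ignore.case = TRUE) |
                 grepl("ectomycorrhizal", guild, ignore.case = TRUE))
  sap <- ok & !myc & tolower(trophic_mode) == "saprotroph"
  path <- ok & !myc & tolower(trophic_mode) == "pathotroph"
  out[myc] <- "mycorrhizal"
  out[sap] <- "saprotrophic"
  out[path] <- "pathotrophic"
  out
}

#' Partition an OTU table by functional guild
#'
#' @param table samples x OTUs count matrix.
#' @param annotation annotation data.frame (`otu_id`, `trophic_mode`,
#'   `guild`, `confidence`).  Table OTUs absent from the annotation are
#'   treated as Unassigned; annotation rows for OTUs not in the table raise a
#'   warning and are ignored.
#' @return named list of OTU tables: `total` (input unchanged),
#'   `mycorrhizal`, `saprotrophic`, `pathotrophic` (pairwise-disjoint OTU
#'   sets, original counts).
#' @export
partition_table <- function(table, annotation) {
  table <- validate_otu_table(table)
  extra <- setdiff(annotation$otu_id, colnames(table))
  if (length(extra))
    warning(sprintf("annotation references %d OTU(s) not in the table (e.g. '%s')",
                    length(extra), extra[1L]))
  cls <- stats::setNames(classify_otu(annotation$trophic_mode, annotation$guild,
                                      annotation$confidence),
                         annotation$otu_id)
  assign_of <- function(ids) {
    out <- cls[ids]
    out[is.na(out)] <- "excluded"  # unannotated = Unassigned = excluded
    out
  }
  a <- assign_of(colnames(table))
  pick <- function(g) table[, a == g, drop = FALSE]
  list(total = table,
       mycorrhizal = pick("mycorrhizal"),
       saprotrophic = pick("saprotrophic"),
       pathotrophic = pick("pathotrophic"))
}

#' Summarize a guild partition
#'
#' @param partition result of [partition_table()].
#' @return data.frame with per-guild OTU count and fraction of the total
#'   sequence count.
#' @export
guild_summary <- function(partition) {
  stopifnot(is.list(partition), "total" %in% names(partition))
  tot <- sum(partition$total)
  if (tot == 0) stop_ga("total table has zero sequences; fractions undefined")
  gs <- setdiff(names(partition), "total")
  data.frame(guild = c("total", gs),
             n_otus = vapply(partition[c("total", gs)], ncol, integer(1)),
             n_sequences = vapply(partition[c("total", gs)], sum, numeric(1)),
             fraction = vapply(partition[c("total", gs)], sum, numeric(1)) / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}
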