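# Fixed shape of the six-taxon primate chronogram. Branches are labelled by
# the node immediately below them; marmoset is the outgroup and carries no
# branch in the model.
.BRANCHES <- c("h", "c", "g", "o", "m", "hc", "hcg", "hcgo", "hcgom")
.PARENT <- c(h = "hc", c = "hc", g = "hcg", o = "hcgo", m = "hcgom",
             hc = "hcg", hcg = "hcgo", hcgo = "hcgom", hcgom = NA)
.TIPS <- c("h", "c", "g", "o", "m")
.TIP_ORDER <- c("human", "chimp", "gorilla", "orangutan", "macaque", "marmoset")
.TIP_LETTER <- c(human = "h", chimp = "c", gorilla = "g",
                 orangutan = "o", macaque = "m")

.children_map <- function() {
  ch <- lapply(.BRANCHES, function(b) .BRANCHES[!is.na(.PARENT) & .PARENT == b])
  names(ch) <- .BRANCHES
  ch
}

.tips_below <- function(branch) .TIPS_BELOW[[branch]]

.STATE_COLS <- paste0("u_", .TIP_ORDER)

# precomputed descendant-tip sets (constant topology)
.TIPS_BELOW <- local({
  ch <- .children_map()
  below <- function(b) {
    if (b %in% .TIPS) return(b)
    unlist(lapply(ch[[b]], below))
  }
  out <- lapply(.BRANCHES, function(b) .TIPS[.TIPS %in% below(b)])
  names(out) <- .BRANCHES
  out
})

.SUPPORT_KEY <- vapply(.BRANCHES,
                       function(b) paste(.TIPS_BELOW[[b]], collapse = ","), "")
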