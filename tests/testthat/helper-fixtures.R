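## Shared in-code fixtures; everything is generated at test time.

## small genes x samples matrix with labels
mkExpr <- function(values, nGenes, nSamples,
                   genes = sprintf("g%02d", seq_len(nGenes)),
                   samples = sprintf("s%02d", seq_len(nSamples))) {
    matrix(values, nGenes, nSamples, dimnames = list(genes, samples))
}

## thesaurus over plain single-token gene/concept surfaces
mkThesaurus <- function(geneIds, conceptIds = character(),
                        conceptType = "phenotype") {
    simulateThesaurus(geneIds, conceptIds, conceptType = conceptType)
}

## co-occurrence network built directly from per-document term sets
netFromDocs <- function(docTerms, thes) {
    txt <- vapply(docTerms, paste, character(1L), collapse = " ")
    buildNetwork(corpus(sprintf("d%03d", seq_along(docTerms)), txt), thes)
}

## brute-force conservation count: sum over docs of choose(m_d, 2)
pairBudget <- function(docTerms) {
    sum(vapply(docTerms, function(d) choose(length(unique(d)), 2),
               numeric(1L)))
}
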