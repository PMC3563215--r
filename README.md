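# domaincut

Protein domain boundary prediction from residue–residue contact maps, with
baseline predictors and the normalized domain overlap (NDO) assessment
score.

## The problem

Multidomain proteins fold into compact, semi-independent structural units.
Locating the boundaries between domains from sequence-derived information
alone is a long-standing problem: boundary positions are needed to split
targets for structure prediction, to assign function, and to design
constructs. Predicted residue–residue contacts carry a strong boundary
signal — residues within one domain are in contact far more often than
residues in different domains — and `domaincut` turns that signal into
explicit cut points.

## The method

For a chain of length *L* with a ranked contact list (the top 1000
contacts after removing pairs closer than 5 residues in sequence), the
predictor builds a **contact-cut profile**: for every contact (*i*, *j*) a
Gaussian kernel of standard deviation σ (the bandwidth) is centered on
each residue strictly between *i* and *j*, and the summed density is
normalized to a per-residue probability

> f(p) ∝ Σ₍i,j₎ Σ₍i<r<j₎ φ((p − r)/σ),  p = 1…L.

f(p) estimates how many predicted contacts a cut at residue *p* would
disrupt; its local minima — found with a least-squares slope estimate over
a window of 5 residues either side — are the predicted cut points. The
default bandwidth is σ = L/15, with fixed, logarithmic, power-law and
AMISE plug-in schemes available for comparison sweeps.

The package also provides:

* **pseudo-Cβ structure contacts** — contacts derived from Cα-only models
  by placing a pseudo-Cβ 2 Å from each Cα away from the local backbone
  line, with an 8 Å contact threshold;
* a **naive Bayesian baseline** — P(N | L) from class priors and
  Gaussian-KDE length likelihoods, mixed with 1000-cell boundary-position
  profiles scaled to the query length;
* a **homology endpoint baseline** — alignment start/end positions
  accumulated into a profile, smoothed by repeated averaging, with peaks
  accepted greedily no closer than 60 residues to a terminus or to each
  other;
* the **NDO score** — per-residue agreement between predicted and
  reference domain labelings after stable-marriage (Gale–Shapley) label
  matching on the overlap matrix, truncated to [0, 100], in a `balanced`
  (100·(2M − l)/l) and a `fraction` (100·M/l) variant;
* seeded **synthetic generators** for contact maps with intra/inter-domain
  contrast, ideal-helix coordinates, length-model training sets and
  alignment endpoints, so everything is testable without downloads.

## Worked example

```r
library(domaincut)

spec <- sim_spec(c(60, 60))                  # two 60-residue domains
sim  <- generate_multidomain_contacts(spec, seed = 1)
pred <- predict_domains_kde(sim$contacts)    # filter, smooth (L/15), cut
pred
#> KDE domain prediction: L = 120 residues, 2 domain(s)
#>   sigma = 8 | contacts used = 195
#>   chopping: 1-60/61-120

ndo_score(sim$annotation, pred)
#> NDO score (balanced): 100  [raw 100]
#>   matched residues M = 120 of l = 120 jointly labeled
#>   label matching (ref -> pred): 1->1, 2->2
```

The predictor recovered the true boundary at residue 61 exactly, so all
120 residues agree after label matching and the NDO score is 100. With the
default noisy generator settings, the bandwidth controls the usual
trade-off: `bandwidth = "fixed:1"` undersmooths and overpredicts domains,
`"fixed:50"` oversmooths toward single-domain calls.

A command-line wrapper for all steps is installed at
`system.file("cli/domaincut.R", package = "domaincut")` (subcommands
`predict-kde`, `predict-naive`, `predict-homology`, `fit-length-model`,
`contacts-from-structure`, `score-ndo`, `simulate-*`, `benchmark`).

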