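# Vocabulary constants shared across modules (collates first).

RDF_TYPE   <- "rdf:type"
RDFS_LABEL <- "rdfs:label"

# object properties
P_HAS_PART      <- "EX:hasPart"
P_PART_OF       <- "EX:partOf"
P_BEARER_OF     <- "EX:bearerOf"
P_INHERES_IN    <- "EX:inheresIn"
P_HAS_COMPONENT <- "EX:hasComponent"
P_INCREASED     <- "EX:increasedInMagnitudeRelativeTo"
P_HAS_NOT_PART  <- "EX:hasNotPartAny"   # not OWL-expressible; flagged non-DL
P_TOWARDS_CLASS <- "EX:towardsClass"    # not OWL-expressible; flagged non-DL
P_HAS_VALUE     <- "EX:hasValue"
P_HAS_UNIT      <- "EX:hasUnit"
P_ABOUT         <- "EX:about"
P_SUPERSEDES    <- "EX:supersedes"

# perceptual / structural categories used to classify named graphs
CAT_PARTHOOD      <- "EX:catParthood"
CAT_INSTANTIATION <- "EX:catInstantiation"
CAT_MEASUREMENT   <- "EX:catMeasurement"
CAT_WEIGHT        <- "EX:catWeight"
CAT_LENGTH        <- "EX:catLength"
CAT_VOLUME        <- "EX:catVolume"
CAT_POSITION      <- "EX:catPosition"
CAT_COLOR         <- "EX:catColor"
CAT_SHAPE         <- "EX:catShape"
CAT_FUNCTION      <- "EX:catFunction"
CAT_DEVELOPMENT   <- "EX:catDevelopment"

C_ANATOMICAL <- "UBERON:0001062"
C_QUALITY    <- "EX:quality"
C_UNIT       <- "EX:unit"

FIXTURE_PREFIXES <- c(
  UBERON = "http://purl.obolibrary.org/obo/UBERON_",
  PATO   = "http://purl.obolibrary.org/obo/PATO_",
  MA     = "http://purl.obolibrary.org/obo/MA_",
  MP     = "http://purl.obolibrary.org/obo/MP_",
  EX     = "http://example.org/phenokg/vocab#",
  PHENO  = "http://example.org/phenokg/class/",
  rdf    = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs   = "http://www.w3.org/2000/01/rdf-schema#",
  owl    = "http://www.w3.org/2002/07/owl#",
  xsd    = "http://www.w3.org/2001/XMLSchema#"
)

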