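# Species registry: photopigment peak wavelengths (lambda_max, nm, 11-cis
# A1 chromophore) per photoreceptor class, plus a parametric lens model per
# species. Absent photoreceptor classes (e.g. no S-cone in Syrian hamster,
# no separate L-cone in most non-primates) are omitted, not zeroed.
#
# Lens entries are synthetic logistic stand-ins (lambda50 = wavelength of
# half-maximal transmission, width = logistic steepness in nm), chosen to
# reflect the species' published short-wavelength lens cutoff class:
# UV-transmissive lenses for the small rodents with UV S-cones, and
# UV-blocking lenses for the larger mammals and primates.
species:
  - name: Mouse
    latin_name: Mus musculus
    photoreceptors: {s_cone: 358, melanopsin: 480, rod: 498, m_cone: 508}
    lens: {lambda50: 339, width: 10}
  - name: Four-striped grass mouse
    latin_name: Rhabdomys pumilio
    photoreceptors: {s_cone: 360, melanopsin: 476, rod: 493, m_cone: 501}
    lens: {lambda50: 358, width: 10}
  - name: Brown rat
    latin_name: Rattus norvegicus
    photoreceptors: {s_cone: 358, melanopsin: 481, rod: 498, m_cone: 509}
    lens: {lambda50: 339, width: 10}
  - name: Syrian hamster
    latin_name: Mesocricetus auratus
    photoreceptors: {melanopsin: 479, rod: 502, m_cone: 504}
    lens: {lambda50: 345, width: 10}
  - name: Mongolian gerbil
    latin_name: Meriones unguiculatus
    photoreceptors: {s_cone: 360, melanopsin: 491, rod: 502, m_cone: 490}
    lens: {lambda50: 354, width: 10}
  - name: Cattle
    latin_name: Bos taurus
    photoreceptors: {s_cone: 435, melanopsin: 484, rod: 500, m_cone: 553}
    lens: {lambda50: 420, width: 15}
  - name: Sheep
    latin_name: Ovis aries
    photoreceptors: {s_cone: 440, melanopsin: 484, rod: 500, m_cone: 549}
    lens: {lambda50: 420, width: 15}
  - name: Horse
    latin_name: Equus ferus caballus
    photoreceptors: {s_cone: 428, melanopsin: 482, rod: 499, m_cone: 545}
    lens: {lambda50: 414, width: 15}
  - name: Cat
    latin_name: Felis catus
    photoreceptors: {s_cone: 450, melanopsin: 488, rod: 501, m_cone: 553}
    lens: {lambda50: 398, width: 12}
  - name: Dog
    latin_name: Canis lupus familiaris
    photoreceptors: {s_cone: 428, melanopsin: 488, rod: 506, m_cone: 554}
    lens: {lambda50: 406, width: 12}
  - name: Rabbit
    latin_name: Oryctolagus cuniculus
    photoreceptors: {s_cone: 421, melanopsin: 488, rod: 502, m_cone: 509}
    lens: {lambda50: 404, width: 12}
  - name: Crab-eating macaque
    latin_name: Macaca fascicularis
    photoreceptors: {s_cone: 415, melanopsin: 483, rod: 500, m_cone: 535, l_cone: 567}
    lens: {lambda50: 424, width: 12}
  - name: Degu
    latin_name: Octodon degus
    photoreceptors: {s_cone: 362, melanopsin: 482, rod: 503, m_cone: 502}
    lens: {lambda50: 362, width: 10}
  - name: Human
    latin_name: Homo sapiens
    # CIE-derived in-vivo alpha-opic peaks used directly as template inputs
    # with the standard adult lens model.
    photoreceptors: {s_cone: 447, melanopsin: 488, rod: 504, m_cone: 540, l_cone: 565}
    lens: {lambda50: 420, width: 12}
    human: true
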