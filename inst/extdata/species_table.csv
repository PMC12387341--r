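code,scientific_name,family,common_name
Aj,Albizia julibrissin,Fabaceae,Silk tree
Af,Amorpha fruticosa,Fabaceae,False indigo bush
Csin,Camellia sinensis,Theaceae,Tea camellia
Csie,Castanopsis sieboldii,Fagaceae,Siebold's chinquapin
Co,Chamaecyparis obtusa,Cupressaceae,Hinoki Cypress
Cc,Cinnamomum chekiangense,Lauraceae,Japanese camphor tree
Dt,Dendropanax trifidus,Araliaceae,Korean dendropanax
Eu,Eucommia ulmoides,Eucommiaceae,Gutta percha
Ico,Ilex cornuta,Aquifoliaceae,Horned holly
Icr,Ilex crenata,Aquifoliaceae,Box-leaf holly
Ik,Indigofera kirilowii,Fabaceae,Kirilow's indigo
Ip,Indigofera pseudotinctoria,Fabaceae,Dwarf false-indigo
Lb,Lespedeza bicolor,Fabaceae,Shrub lespedeza
Lc,Lespedeza cyrtobotrya,Fabaceae,Leafy lespedeza
Lj,Ligustrum japonicum,Oleaceae,Wax-leaf privet
Mb,Morus bombycis,Moraceae,Korean mulberry
Ns,Neolitsea sericea,Lauraceae,Sericeous newlitsea
Pr,Pinus rigida,Pinaceae,Pitch pine
Qa,Quercus acuta,Fagaceae,Red-wood evergreen oak
Qg,Quercus glauca,Fagaceae,Ring-cup oak
Qm,Quercus myrsinaefolia,Fagaceae,Bamboo-leaf oak
Qp,Quercus phillyraeoides,Fagaceae,Ubame oak
Qs,Quercus salicina,Fagaceae,Willow-leaf evergreen oak
Rp,Robinia pseudoacacia,Fabaceae,Black locust
Ss,Sorbaria sorbifolia var. stellipila,Rosaceae,False spiraea
Sp,Spiraea prunifolia f. simpliciflora,Rosaceae,Simple bridalwreath spiraea
Tj,Ternstroemia japonica,Pentaphylacaceae,Naked-anther ternstroemia
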