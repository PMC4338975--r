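family,invasive_species,native_species,block
Asteraceae,Conyza canadensis,Pseudognaphalium sandwicensium,family
Asteraceae,Ageratina riparia,Dubautia scabra,family
Asteraceae,Hypochoeris radicata,Argyroxiphium kauense,family
Fabaceae,Desmodium sandwicense,Sesbania tomentosa,family
Fabaceae,Leucaena leucocephala,Sophora chrysophylla,family
Fabaceae,Prosopis pallida,Erythrina sandwicensis,family
Myrtaceae,Psidium cattleianum,Metrosideros polymorpha,family
Nephrolepidaceae,Nephrolepsis multiflora,Nephrolepsis cordifolia,family
Oleaceae,Olea europaea,Nestegis sandwicensis,family
Plantaginaceae,Plantago lanceolata,Plantago hawaiiensis,family
Poaceae,Rhynchelytrum repens,Heteropogon contortus,family
Poaceae,Ehrharta stipoides,Isachne distichophylla,family
Poaceae,Holcus lanatus,Deschampsia nubigena,family
Poaceae,Paspalum urvillei,Eragrostis variabilis,family
Rosaceae,Pyracantha angustifolia,Osteomeles anthyllidifolia,family
Rosaceae,Rubus ellipticus,Rubus hawaiiensis,family
Solanaceae,Nicotiana glauca,Nothocestrum brevifolia,family
Sapindales,Schinus terebinthifolius,Dodonaea viscosa,within_order
Asparagales,Crocosmia pottsii x aurea,Astelia menziesiana,within_order
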