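# Nigeria, 30 pre-1996 states + Abuja (FCT); post-1996 split pairs merged.
# Format: region count; then per region: id, neighbour count, neighbour ids.
31
Sokoto/Zamfara 4 Kebbi Katsina Kaduna Niger
Kebbi 2 Sokoto/Zamfara Niger
Katsina 4 Sokoto/Zamfara Kaduna Kano Jigawa
Kano 4 Katsina Jigawa Kaduna Bauchi/Gombe
Jigawa 4 Katsina Kano Bauchi/Gombe Yobe
Yobe 3 Jigawa Bauchi/Gombe Borno
Borno 3 Yobe Bauchi/Gombe Adamawa
Adamawa 3 Borno Bauchi/Gombe Taraba
Bauchi/Gombe 8 Kano Jigawa Yobe Borno Adamawa Taraba Nassarawa/Plateau Kaduna
Kaduna 7 Sokoto/Zamfara Katsina Kano Bauchi/Gombe Nassarawa/Plateau Niger Abuja
Nassarawa/Plateau 6 Kaduna Bauchi/Gombe Taraba Benue Kogi Abuja
Taraba 4 Adamawa Bauchi/Gombe Nassarawa/Plateau Benue
Niger 6 Kebbi Sokoto/Zamfara Kaduna Abuja Kogi Kwara
Abuja 4 Kaduna Niger Nassarawa/Plateau Kogi
Kogi 9 Niger Abuja Nassarawa/Plateau Benue Enugu/Ebonyi Anambra Edo Ondo/Ekiti Kwara
Kwara 5 Niger Kogi Oyo Osun Ondo/Ekiti
Oyo 3 Kwara Ogun Osun
Osun 4 Oyo Kwara Ondo/Ekiti Ogun
Ogun 4 Lagos Oyo Osun Ondo/Ekiti
Lagos 1 Ogun
Ondo/Ekiti 6 Kwara Kogi Osun Ogun Edo Delta
Edo 4 Kogi Ondo/Ekiti Delta Anambra
Delta 5 Edo Ondo/Ekiti Anambra Imo Rivers/Bayelsa
Anambra 6 Kogi Edo Delta Enugu/Ebonyi Imo Abia
Imo 4 Anambra Delta Abia Rivers/Bayelsa
Abia 6 Imo Anambra Enugu/Ebonyi "Cross River" "Akwa Ibom" Rivers/Bayelsa
Enugu/Ebonyi 5 Kogi Anambra Benue Abia "Cross River"
Benue 5 Kogi Nassarawa/Plateau Taraba Enugu/Ebonyi "Cross River"
"Cross River" 4 Benue Enugu/Ebonyi Abia "Akwa Ibom"
"Akwa Ibom" 3 "Cross River" Abia Rivers/Bayelsa
Rivers/Bayelsa 4 Delta Imo Abia "Akwa Ibom"
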